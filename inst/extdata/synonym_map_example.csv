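verbatim,standardized,is_combination
LISINOPRIL,lisinopril,FALSE
LISINOPRIL 10MG TAB,lisinopril,FALSE
ZESTRIL,lisinopril,FALSE
ENALAPRIL MALEATE,enalapril,FALSE
VASOTEC,enalapril,FALSE
RAMIPRIL,ramipril,FALSE
ALTACE,ramipril,FALSE
ACTIVASE,alteplase,FALSE
ALTEPLASE,alteplase,FALSE
AMOXICILLIN,amoxicillin,FALSE
AMOXIL,amoxicillin,FALSE
amoxicillin/clavulanate,amoxicillin potassium clavulanate combination,TRUE
AUGMENTIN,amoxicillin potassium clavulanate combination,TRUE
ZESTORETIC,hydrochlorothiazide and lisinopril,TRUE
IBUPROFEN,ibuprofen,FALSE
ADVIL,ibuprofen,FALSE
TYLENOL,paracetamol,FALSE
ACETAMINOPHEN,paracetamol,FALSE
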