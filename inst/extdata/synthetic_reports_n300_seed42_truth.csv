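drug,theta
lisinopril,1
enalapril,1
perindopril,1
ramipril,1
losartan,1
valsartan,1
amlodipine,1
hydrochlorothiazide and lisinopril,1
alteplase,1
carbasalate calcium,1
ibuprofen,1
naproxen,1
paracetamol,1
diclofenac,1
celecoxib,1
pregabalin,1
amoxicillin,1
amoxicillin potassium clavulanate combination,1
clarithromycin,1
lansoprazole,1
omeprazole,1
infliximab,1
secukinumab,1
etanercept,1
adalimumab,1
lenalidomide,1
sitagliptin phosphate,1
cetirizine,1
omalizumab,1
montelukast,1
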