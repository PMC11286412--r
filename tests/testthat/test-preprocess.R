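test_that("exact duplicates collapse to a single record", {
  r <- make_reports(c("R1", "R2"), case_id = "C1",
                    drugs = list(c("aspirin", "lisinopril")))
  out <- deduplicate(r)
  expect_equal(nrow(out), 1)
  expect_equal(out$report_id, "R2")  # greatest report_id wins the tie
  expect_equal(attr(out, "n_removed"), 1L)
})

test_that("only the latest report per case and medication survives", {
  r <- make_reports(c("R1", "R2"), case_id = "C1", drugs = list("drug x"),
                    receipt_date = as.Date(c("2020-01-01", "2021-01-01")))
  out <- deduplicate(r)
  expect_equal(out$report_id, "R2")
  # a missing date sorts earliest: dated evidence preferred
  r2 <- make_reports(c("R8", "R9"), case_id = "C1", drugs = list("drug x"),
                     receipt_date = as.Date(c("2020-01-01", NA)))
  expect_equal(deduplicate(r2)$report_id, "R8")
})

test_that("deduplication is idempotent and a no-op without duplicates", {
  clean <- strip_truth(generate_reports(
    synthetic_config(n_reports = 100, seed = 5, dup_rate = 0)))
  out <- deduplicate(clean)
  expect_equal(nrow(out), 100)
  once <- deduplicate(generate_reports(
    synthetic_config(n_reports = 200, seed = 6, dup_rate = 0.2)))
  twice <- deduplicate(once)
  expect_equal(strip_book(twice), strip_book(once))
})

test_that("dedup output size equals the brute-force distinct-key count", {
  base <- generate_reports(synthetic_config(n_reports = 100, seed = 8,
                                            dup_rate = 0))
  dups <- base[rep(1:10, 2), ]  # 20 extra copies of 10 reports
  dups$report_id <- paste0(dups$report_id, "X", seq_len(20))
  mixed <- dplyr::bind_rows(base, dups)[sample(120), ]
  out <- deduplicate(mixed)
  key <- vapply(seq_len(nrow(mixed)), function(i) {
    paste(mixed$case_id[i], mixed$receipt_date[i],
          paste(sort(unique(mixed$drug_standardized[[i]])), collapse = "+"))
  }, "")
  expect_equal(nrow(out), length(unique(key)))
})

test_that("dedup result does not depend on input row order", {
  r <- generate_reports(synthetic_config(n_reports = 150, seed = 9,
                                         dup_rate = 0.3))
  a <- deduplicate(r)
  b <- deduplicate(r[rev(seq_len(nrow(r))), ])
  b <- b[match(a$report_id, b$report_id), ]
  expect_equal(strip_book(a), strip_book(b))
})

test_that("standardization resolves names case-insensitively and flags the rest", {
  map <- synonym_map(
    verbatim = c("lisinopril 10mg tab", "amoxicillin/clavulanate"),
    standardized = c("lisinopril", "amoxicillin potassium clavulanate combination"),
    combinations = "amoxicillin potassium clavulanate combination"
  )
  r <- make_reports("R1", drugs = list(c(
    "LISINOPRIL 10MG TAB", "amoxicillin/clavulanate", "herbal blend X"
  )), standardized = FALSE)
  out <- standardize_drugs(r, map)
  expect_equal(out$drug_standardized[[1]],
               c("lisinopril", "amoxicillin potassium clavulanate combination",
                 NA))
  expect_equal(out$drug_combination[[1]], c(FALSE, TRUE, NA))
  expect_equal(nrow(out), 1)  # unresolved entries never drop the record
  expect_warning(standardize_drugs(r, synonym_map()), "empty synonym map")
})

test_that("exclusions drop matching drug entries and emptied reports", {
  r <- make_reports(c("R1", "R2"),
                    drugs = list("bad drug", c("bad drug", "aspirin")))
  out <- exclude_drugs(r, "bad drug")
  expect_equal(out$report_id, "R2")
  expect_equal(out$drug_standardized[[1]], "aspirin")
  expect_equal(attr(out, "n_reports_removed"), 1L)
  expect_equal(attr(out, "n_drugs_removed"), 2L)
  ident <- exclude_drugs(r, character())
  expect_equal(strip_book(ident), strip_book(r))
})

test_that("event matching is exact on the PT, case- and order-insensitive", {
  r <- make_reports(
    c("R1", "R2", "R3"),
    drugs = list("x"),
    reactions = list(c("Angioedema", "Rash"), c("Rash", "ANGIOEDEMA "),
                     "Angioedema hereditary")
  )
  expect_equal(match_event(r, "angioedema"), c(TRUE, TRUE, FALSE))
  expect_equal(match_event(r, "Angioedema"), c(TRUE, TRUE, FALSE))
  expect_error(match_event(r, ""), "nzchar")
})

test_that("most severe outcome follows the fixed severity order", {
  expect_equal(most_severe_outcome(c("HO", "DE")), "DE")
  expect_equal(most_severe_outcome("OT"), "OT")
  expect_true(is.na(most_severe_outcome(character())))
  expect_equal(most_severe_outcome(c("OT", "RI", "CA", "DS", "HO", "LT")), "LT")
})

test_that("the cleaning report is monotone along the pipeline", {
  r <- generate_reports(synthetic_config(n_reports = 400, seed = 10,
                                         dup_rate = 0.15))
  cleaned <- clean_reports(r, exclusions = "paracetamol",
                           event_pt = "Angioedema")
  cr <- cleaning_report(cleaned)
  expect_true(cr$n_input >= cr$n_after_dedup)
  expect_true(cr$n_after_dedup >= cr$n_after_exclusion)
  expect_equal(cr$n_after_exclusion, nrow(cleaned))
  expect_equal(cr$n_event_matched, sum(match_event(cleaned, "Angioedema")))
})
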