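# Construct a small report tibble by hand. `drugs` and `reactions` are lists
# of character vectors; scalar arguments are recycled.
make_reports <- function(report_id, drugs, reactions = list("Angioedema"),
                         case_id = report_id,
                         receipt_date = as.Date("2020-01-01"),
                         age_years = NA_real_, sex = NA_character_,
                         occupation = NA_character_, country = NA_character_,
                         outcomes = list(character()), standardized = TRUE) {
  n <- length(report_id)
  rcy <- function(x) rep_len(x, n)
  drugs <- rep_len(drugs, n)
  tibble::tibble(
    report_id = report_id,
    case_id = rcy(case_id),
    receipt_date = rcy(receipt_date),
    age_years = rcy(age_years),
    sex = rcy(sex),
    occupation = rcy(occupation),
    country = rcy(country),
    drug_verbatim = lapply(drugs, toupper),
    drug_standardized = if (standardized) drugs else
      lapply(drugs, function(d) rep(NA_character_, length(d))),
    drug_combination = lapply(drugs, function(d) rep(FALSE, length(d))),
    reactions = rep_len(reactions, n),
    outcomes = rep_len(outcomes, n)
  )
}

# Brute-force four-fold counts: an explicit double loop over reports,
# independent of the package's vectorized counting.
oracle_contingency <- function(reports, drug, event) {
  a <- b <- c <- d <- 0L
  drug <- tolower(trimws(drug)); event <- tolower(trimws(event))
  for (i in seq_len(nrow(reports))) {
    std <- reports$drug_standardized[[i]]
    verb <- reports$drug_verbatim[[i]]
    nm <- tolower(trimws(ifelse(is.na(std), verb, std)))
    has_d <- FALSE
    for (x in nm) if (x == drug) has_d <- TRUE
    has_e <- FALSE
    for (x in reports$reactions[[i]]) {
      if (tolower(trimws(x)) == event) has_e <- TRUE
    }
    if (has_d && has_e) a <- a + 1L
    else if (has_d) b <- b + 1L
    else if (has_e) c <- c + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c, d = d)
}

# Independent log-odds-ratio and Wald SE via a saturated binomial GLM. The
# closed-form estimate seeds the IRLS so Fisher scoring verifies it as the
# likelihood's fixed point and reports the information-based SE at machine
# precision.
oracle_logor <- function(a, b, c, d) {
  df <- data.frame(exposed = c(1, 1, 0, 0), event = c(1, 0, 1, 0),
                   w = c(a, b, c, d))
  fit <- suppressWarnings(stats::glm(
    event ~ exposed, family = stats::binomial(), weights = w, data = df,
    start = c(log(c / d), log(a * d / (b * c))),
    control = stats::glm.control(epsilon = 1e-14, maxit = 100)
  ))
  co <- summary(fit)$coefficients["exposed", ]
  list(logor = unname(co[1]), se = unname(co[2]))
}

# Independent continuity-corrected chi-square via stats::chisq.test.
oracle_chi2 <- function(a, b, c, d) {
  m <- matrix(c(a, c, b, d), nrow = 2)
  unname(suppressWarnings(stats::chisq.test(m, correct = TRUE)$statistic))
}

strip_truth <- function(reports) {
  attr(reports, "truth") <- NULL
  attr(reports, "duplicate_of") <- NULL
  reports
}

# Drop bookkeeping attributes before whole-table comparisons.
strip_book <- function(reports) {
  for (a in c("truth", "duplicate_of", "n_removed", "n_drugs_removed",
              "n_reports_removed", "cleaning_report", "read_problems")) {
    attr(reports, a) <- NULL
  }
  as.data.frame(reports)
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  expect_true(all(abs(actual - expected) <=
                    tol * pmax(abs(expected), 1e-12)),
              label = paste0("relative agreement within ", tol))
}
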