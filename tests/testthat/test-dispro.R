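fourfold <- function(a, b, c, d) tibble::tibble(a = a, b = b, c = c, d = d)

test_that("contingency cells partition tiny exhaustive datasets", {
  r <- make_reports(
    paste0("R", 1:4), drugs = list("x", "x", "y", "y"),
    reactions = list("Angioedema", "Rash", "Angioedema", "Rash")
  )
  ct <- build_contingency(r, "x", "Angioedema")
  expect_equal(unlist(ct[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))
  # every report exposed: the unexposed margin is empty
  r2 <- make_reports(paste0("R", 1:3), drugs = list("x"),
                     reactions = list("Angioedema", "Rash", "Rash"))
  ct2 <- build_contingency(r2, "x", "Angioedema")
  expect_equal(unlist(ct2[c("c", "d")]), c(c = 0, d = 0))
  # a drug absent from the data yields an empty exposed margin, no error
  ct3 <- build_contingency(r2, "zzz", "Angioedema")
  expect_equal(ct3$a + ct3$b, 0)
})

test_that("a report naming a drug twice counts once per cell", {
  r <- make_reports("R1", drugs = list(c("x", "x")),
                    reactions = list("Angioedema"))
  ct <- build_contingency(r, "x", "Angioedema")
  expect_equal(ct$a, 1)
  expect_equal(ct$n, 1)
})

test_that("contingency counts match the brute-force double loop", {
  r <- generate_reports(synthetic_config(
    n_reports = 5000, seed = 11,
    drug_event_or = c(lisinopril = 10, ibuprofen = 2)
  ))
  for (drug in c("lisinopril", "ibuprofen", "omeprazole")) {
    ct <- build_contingency(r, drug, "Angioedema")
    expect_equal(unlist(ct[c("a", "b", "c", "d")]),
                 oracle_contingency(r, drug, "Angioedema"), label = drug)
  }
})

test_that("ROR, CI and PRR reproduce the frozen worked example", {
  t <- fourfold(10, 90, 100, 9900)
  ror <- compute_ror(t)
  expect_equal(ror$ror, 11.0)
  expect_equal(round_half_up(ror$ci_lower, 2), 5.56)
  expect_equal(round_half_up(ror$ci_upper, 2), 21.76)
  expect_equal(ror$se_log, sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900))
  prr <- compute_prr(t)
  expect_equal(prr$prr, 10.0)
  expect_equal(round_half_up(prr$chi2, 1), 66.3)
})

test_that("perfect independence gives ROR 1 with a log-symmetric CI", {
  res <- compute_ror(fourfold(25, 25, 25, 25))
  expect_equal(res$ror, 1.0)
  expect_equal(res$ci_lower * res$ci_upper, 1.0, tolerance = 1e-12)
})

test_that("zero cells are undefined by default, defined under Haldane", {
  t <- fourfold(3, 0, 5, 100)
  none <- compute_ror(t)
  expect_false(none$ror_defined)
  expect_true(is.na(none$ror))
  hald <- compute_ror(t, zero_cell = "haldane")
  expect_true(hald$ror_defined)
  expect_equal(hald$ror, (3.5 * 100.5) / (0.5 * 5.5))
  # tables without zeros are untouched by the Haldane policy
  t2 <- fourfold(10, 90, 100, 9900)
  expect_equal(compute_ror(t2, zero_cell = "haldane")$ror,
               compute_ror(t2)$ror)
})

test_that("chi-square clamps to zero when the correction overshoots", {
  expect_equal(compute_prr(fourfold(1, 1, 1, 1))$chi2, 0)
  expect_equal(oracle_chi2(1, 1, 1, 1), 0)
  expect_true(is.na(compute_prr(fourfold(5, 0, 3, 0))$chi2))
  expect_false(compute_prr(fourfold(5, 5, 0, 10))$prr_defined)
})

test_that("ROR/PRR/chi2 agree with independent routines to 1e-9 relative", {
  set.seed(2024)
  tabs <- tibble::tibble(
    a = sample(1:400, 80, TRUE), b = sample(1:2000, 80, TRUE),
    c = sample(1:400, 80, TRUE), d = sample(1:50000, 80, TRUE)
  )
  res <- compute_prr(compute_ror(tabs))
  for (i in seq_len(nrow(tabs))) {
    o <- oracle_logor(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_rel_equal(log(res$ror[i]), o$logor, 1e-9)
    expect_rel_equal(res$se_log[i], o$se, 1e-9)
    expect_rel_equal(res$chi2[i],
                     oracle_chi2(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]),
                     1e-9)
  }
})

test_that("the signal decision combines both criteria as a disjunction", {
  mk <- function(a, ci_lower, prr, chi2) {
    tibble::tibble(a = a, ci_lower = ci_lower, ror_defined = !is.na(ci_lower),
                   prr = prr, chi2 = chi2, prr_defined = !is.na(prr))
  }
  expect_true(evaluate_signal(mk(10, 5.56, 10, 66.3))$signal)
  # below the minimum report count nothing fires
  expect_false(evaluate_signal(mk(2, 5.56, 10, 66.3))$signal)
  # PRR branch alone suffices
  dec <- evaluate_signal(mk(50, 0.9, 2.5, 10))
  expect_false(dec$ror_criterion_met)
  expect_true(dec$prr_criterion_met)
  expect_true(dec$signal)
  # boundary: criteria are inclusive at PRR=2, chi2=4, but ci_lower>1 strict
  expect_true(evaluate_signal(mk(3, 0.5, 2, 4))$signal)
  expect_false(evaluate_signal(mk(3, 1, 1.9, 3.9))$signal)
  # undefined statistics never fire
  expect_false(evaluate_signal(mk(10, NA, NA, NA))$signal)
})

test_that("point_from_ci inverts the log-symmetric interval", {
  expect_equal(round_half_up(point_from_ci(42.59, 50.62), 2), 46.43)
  expect_equal(round_half_up(point_from_ci(19.66, 22.28), 2), 20.93)
  expect_equal(point_from_ci(7.3, 7.3), 7.3)
  expect_error(point_from_ci(-1, 2), "positive")
  expect_error(point_from_ci(3, 2), "exceed")
})

test_that("CI self-consistency: the point estimate is the CI geometric mean", {
  set.seed(31)
  tabs <- tibble::tibble(
    a = sample(1:100, 50, TRUE), b = sample(1:1000, 50, TRUE),
    c = sample(1:100, 50, TRUE), d = sample(1:10000, 50, TRUE)
  )
  res <- compute_ror(tabs)
  expect_rel_equal(point_from_ci(res$ci_lower, res$ci_upper), res$ror, 1e-9)
})

test_that("increasing a with b, c, d fixed strictly increases ROR and PRR", {
  a <- 1:60
  res <- compute_prr(compute_ror(fourfold(a, 200, 50, 5000)))
  expect_true(all(diff(res$ror) > 0))
  expect_true(all(diff(res$prr) > 0))
})

test_that("screening ranks by report count and flags the injected signal", {
  r <- generate_reports(synthetic_config(
    n_reports = 20000, seed = 12, drug_event_or = c(lisinopril = 20)
  ))
  r <- deduplicate(r)
  sc <- screen_drugs(r, top_n = 30)
  expect_s3_class(sc, "pv_screen")
  expect_true(all(diff(sc$a) <= 0))
  expect_true(sc$signal[sc$drug == "lisinopril"])
  # the null drugs should mostly stay quiet
  expect_lt(mean(sc$signal[sc$drug != "lisinopril"]), 0.2)
  expect_equal(sc$ror_rank[which.max(sc$ror)], 1L)
})

test_that("top_n selection matches a brute-force ranking", {
  r <- generate_reports(synthetic_config(n_reports = 3000, seed = 13))
  sc <- screen_drugs(r, top_n = 10)
  expect_equal(nrow(sc), 10)
  # brute-force ranking by target-event report count, ties alphabetical
  ev <- match_event(r, "Angioedema")
  exposure <- table(unlist(lapply(
    seq_len(nrow(r)),
    function(i) unique(r$drug_standardized[[i]])
  )))
  a_counts <- table(unlist(lapply(
    which(ev),
    function(i) unique(r$drug_standardized[[i]])
  )))
  a_all <- setNames(rep(0L, length(exposure)), names(exposure))
  a_all[names(a_counts)] <- as.integer(a_counts)
  expected <- names(a_all)[order(-a_all, names(a_all))][1:10]
  expect_equal(sc$drug, expected)
  expect_equal(sc$a, unname(a_all[sc$drug]))
  expect_equal(sc$a + sc$b, unname(as.integer(exposure[sc$drug])))
})

test_that("a single-drug dataset screens to a single row", {
  r <- make_reports(paste0("R", 1:5), drugs = list("x"),
                    reactions = list("Angioedema", "Rash", "Rash", "Rash",
                                     "Rash"))
  sc <- screen_drugs(r)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$drug, "x")
  tid <- tidy(sc)
  expect_false(inherits(tid, "pv_screen"))
  gl <- glance(sc)
  expect_equal(gl$n_groups, 1L)
})
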