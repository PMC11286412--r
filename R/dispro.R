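# Normal quantile used for the 95% interval, kept literal by convention.
Z95 <- 1.96

#' Four-fold (2x2) contingency table for one drug-event pair
#'
#' Partitions a cleaned report set by exposure to the target drug and
#' occurrence of the target event:
#' `a` = reports with the drug and the event, `b` = drug without the event,
#' `c` = event without the drug, `d` = neither. The counting unit is the
#' unique report: a report naming the drug several times counts once, and a
#' multi-drug report contributes to the exposed margin of each of its drugs.
#'
#' @param reports Cleaned report tibble.
#' @param drug Standardized drug name (case-insensitive).
#' @param event MedDRA preferred term of the target event.
#' @return One-row tibble with columns `drug, event, a, b, c, d, n`
#'   (`n = a+b+c+d` = number of reports).
#' @examples
#' reports <- generate_reports(synthetic_config(n_reports = 500, seed = 3))
#' build_contingency(reports, "lisinopril", "Angioedema")
#' @export
build_contingency <- function(reports, drug, event) {
  stopifnot_reports(reports)
  has_drug <- list_any_in(drug_name_sets(reports), normalize_label(drug))
  has_event <- match_event(reports, event)
  tibble(
    drug = normalize_label(drug), event = event,
    a = sum(has_drug & has_event), b = sum(has_drug & !has_event),
    c = sum(!has_drug & has_event), d = sum(!has_drug & !has_event),
    n = nrow(reports)
  )
}

check_fourfold <- function(tbl) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tbl)))
  cells <- as.matrix(tbl[c("a", "b", "c", "d")])
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("four-fold cells must be nonnegative integers", call. = FALSE)
  }
  invisible(tbl)
}

#' Reporting odds ratio with Wald 95% confidence interval
#'
#' For each four-fold table row computes `ROR = (a d) / (b c)` and the
#' 95% interval `exp(ln ROR +/- 1.96 * se)` with
#' `se = sqrt(1/a + 1/b + 1/c + 1/d)`. With a zero cell the ratio is
#' undefined under the default policy (`ror_defined = FALSE`, estimates
#' `NA`); the opt-in Haldane-Anscombe policy instead adds 0.5 to every cell
#' of the affected table.
#'
#' @param tbl Tibble with integer columns `a, b, c, d` (one row per table),
#'   e.g. from [build_contingency()] or [screen_drugs()].
#' @param zero_cell `"none"` (default) or `"haldane"`.
#' @return `tbl` with columns `ror`, `ci_lower`, `ci_upper`, `se_log`,
#'   `ror_defined` appended.
#' @examples
#' compute_ror(tibble::tibble(a = 10, b = 90, c = 100, d = 9900))
#' @export
compute_ror <- function(tbl, zero_cell = c("none", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  check_fourfold(tbl)
  # double precision: cell products overflow integer range at FAERS scale
  a <- as.numeric(tbl$a); b <- as.numeric(tbl$b)
  c <- as.numeric(tbl$c); d <- as.numeric(tbl$d)
  any_zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (zero_cell == "haldane") {
    adj <- 0.5 * any_zero
    a <- a + adj; b <- b + adj; c <- c + adj; d <- d + adj
    defined <- rep(TRUE, length(a))
  } else {
    defined <- !any_zero
  }
  ror <- ifelse(defined, (a * d) / (b * c), NA_real_)
  se <- ifelse(defined, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tbl$ror <- ror
  tbl$ci_lower <- exp(log(ror) - Z95 * se)
  tbl$ci_upper <- exp(log(ror) + Z95 * se)
  tbl$se_log <- se
  tbl$ror_defined <- defined
  tbl
}

#' Proportional reporting ratio with continuity-corrected chi-square
#'
#' For each four-fold table row computes
#' `PRR = (a / (a+b)) / (c / (c+d))` and the Yates continuity-corrected
#' chi-square
#' `(|ad - bc| - N/2)^2 N / ((a+b)(c+d)(a+c)(b+d))`,
#' clamped to 0 when the correction overshoots (`|ad - bc| <= N/2`), so a
#' squared corrected statistic never goes negative. The ratio is undefined
#' when either exposure row is empty or `c = 0`; the statistic is `NA` when
#' any table margin is zero.
#'
#' @inheritParams compute_ror
#' @return `tbl` with columns `prr`, `chi2`, `prr_defined` appended.
#' @examples
#' compute_prr(tibble::tibble(a = 10, b = 90, c = 100, d = 9900))
#' @export
compute_prr <- function(tbl) {
  check_fourfold(tbl)
  a <- as.numeric(tbl$a); b <- as.numeric(tbl$b)
  c <- as.numeric(tbl$c); d <- as.numeric(tbl$d)
  n <- a + b + c + d
  defined <- (a + b) > 0 & (c + d) > 0 & c > 0
  tbl$prr <- ifelse(defined, (a / (a + b)) / (c / (c + d)), NA_real_)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  corr <- pmax(abs(a * d - b * c) - n / 2, 0)
  tbl$chi2 <- ifelse(denom > 0, corr^2 * n / denom, NA_real_)
  tbl$prr_defined <- defined
  tbl
}

#' Apply the combined ROR/PRR signal criteria
#'
#' A drug-event pair is a signal when it has at least `min_reports` target
#' reports (`a`) and meets at least one of:
#' \itemize{
#' \item ROR criterion: lower 95% CI bound above 1;
#' \item PRR criterion: `PRR >= 2` and `chi-square >= 4`.
#' }
#'
#' @param tbl Tibble carrying the columns produced by [compute_ror()] and
#'   [compute_prr()].
#' @param min_reports Minimum number of target reports (default 3).
#' @return `tbl` with logical columns `ror_criterion_met`,
#'   `prr_criterion_met`, `signal` appended.
#' @export
evaluate_signal <- function(tbl, min_reports = 3) {
  needed <- c("a", "ci_lower", "ror_defined", "prr", "chi2", "prr_defined")
  stopifnot(all(needed %in% names(tbl)))
  tbl$ror_criterion_met <- tbl$a >= min_reports & tbl$ror_defined &
    !is.na(tbl$ci_lower) & tbl$ci_lower > 1
  tbl$prr_criterion_met <- tbl$a >= min_reports & tbl$prr_defined &
    !is.na(tbl$chi2) & tbl$prr >= 2 & tbl$chi2 >= 4
  tbl$signal <- tbl$ror_criterion_met | tbl$prr_criterion_met
  tbl
}

#' Point estimate from a log-symmetric confidence interval
#'
#' The Wald 95% interval of an odds ratio is symmetric on the log scale, so
#' the point estimate is the geometric mean of its bounds:
#' `exp((ln L + ln U) / 2)`. Useful for recovering (and checking) point
#' estimates from published interval bounds.
#'
#' @param ci_lower,ci_upper Positive interval bounds, `ci_lower <= ci_upper`.
#'   Vectorized.
#' @return Numeric vector of point estimates.
#' @examples
#' point_from_ci(42.59, 50.62)  # ~46.43
#' @export
point_from_ci <- function(ci_lower, ci_upper) {
  if (any(!is.finite(ci_lower) | !is.finite(ci_upper) |
          ci_lower <= 0 | ci_upper <= 0)) {
    stop("interval bounds must be positive", call. = FALSE)
  }
  if (any(ci_lower > ci_upper)) {
    stop("ci_lower must not exceed ci_upper", call. = FALSE)
  }
  exp((log(ci_lower) + log(ci_upper)) / 2)
}

# Shared by screen_drugs() and rollup_categories(): four-fold tables for an
# arbitrary report -> group assignment, counted at report level.
group_tables <- function(reports, group_by_report, event) {
  has_event <- match_event(reports, event)
  n_total <- nrow(reports)
  pairs <- tibble(
    report = rep.int(seq_len(n_total), lengths(group_by_report)),
    group = unlist(group_by_report, use.names = FALSE) %||% character()
  ) |>
    dplyr::distinct()
  pairs |>
    dplyr::mutate(ev = has_event[.data$report]) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_exposed = dplyr::n(), a = sum(.data$ev), .groups = "drop") |>
    dplyr::mutate(
      b = .data$n_exposed - .data$a,
      c = sum(has_event) - .data$a,
      d = n_total - .data$n_exposed - .data$c,
      n = n_total
    ) |>
    dplyr::select("group", "a", "b", "c", "d", "n")
}

#' Screen all drugs for disproportionate event reporting
#'
#' Builds the four-fold table of every drug in the dataset against the target
#' event, ranks drugs by the number of target reports `a` (descending, ties
#' alphabetical), keeps the `top_n` most-reported, and attaches ROR, PRR,
#' chi-square and the combined signal decision. `ror_rank` orders the
#' selected drugs by signal strength (ROR descending).
#'
#' @param reports Cleaned report tibble.
#' @param event Target MedDRA PT (default `"Angioedema"`).
#' @param min_reports Minimum `a` for a signal (default 3).
#' @param top_n Number of most-reported drugs to keep (default 30;
#'   `Inf` keeps all).
#' @param zero_cell Zero-cell policy passed to [compute_ror()].
#' @return A `pv_screen` tibble: one row per selected drug with columns
#'   `drug, a, b, c, d, n, ror, ci_lower, ci_upper, se_log, ror_defined,
#'   prr, chi2, prr_defined, ror_criterion_met, prr_criterion_met, signal,
#'   ror_rank`. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' cfg <- synthetic_config(n_reports = 2000, seed = 42,
#'                         drug_event_or = c(lisinopril = 20))
#' screen_drugs(generate_reports(cfg), top_n = 10)
#' @export
screen_drugs <- function(reports, event = "Angioedema", min_reports = 3,
                         top_n = 30, zero_cell = c("none", "haldane")) {
  stopifnot_reports(reports)
  zero_cell <- match.arg(zero_cell)
  out <- group_tables(reports, drug_name_sets(reports), event) |>
    dplyr::rename(drug = "group") |>
    dplyr::arrange(dplyr::desc(.data$a), .data$drug)
  if (is.finite(top_n)) out <- dplyr::slice_head(out, n = as.integer(top_n))
  out <- out |>
    compute_ror(zero_cell = zero_cell) |>
    compute_prr() |>
    evaluate_signal(min_reports = min_reports) |>
    dplyr::mutate(ror_rank = dplyr::min_rank(dplyr::desc(.data$ror)))
  attr(out, "event") <- event
  attr(out, "min_reports") <- min_reports
  attr(out, "n_reports") <- nrow(reports)
  class(out) <- c("pv_screen", class(out))
  out
}
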