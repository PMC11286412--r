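pct <- function(count, total) {
  if (total == 0) rep(NA_real_, length(count))
  else round_half_up(100 * count / total, 1)
}

na_label <- function(x) ifelse(is.na(x), "NA", x)

#' Demographic composition of a report set
#'
#' Tabulates sex (`F`, `M`, `OTHER`, `NA`), age band (`<18`; `18-60` meaning
#' at least 18 and under 60; `>=60`; `NA`) and reporter occupation
#' (`CONSUMER`, `HEALTH_PROFESSIONAL`, `OTHER`, `NA`). Counts within each
#' variable sum to the dataset total; percentages are
#' `100 * count / total` rounded half-up to one decimal.
#'
#' @param reports Report tibble.
#' @return Tibble with columns `variable`, `stratum`, `count`, `percent`.
#' @export
summarize_demographics <- function(reports) {
  stopifnot_reports(reports)
  total <- nrow(reports)
  if (total == 0) {
    warning("empty report set: empty demographic summary", call. = FALSE)
    return(tibble(variable = character(), stratum = character(),
                  count = integer(), percent = numeric()))
  }
  tab_one <- function(variable, values, levels) {
    values <- factor(na_label(values), levels = levels)
    counts <- table(values)
    tibble(variable = variable, stratum = names(counts),
           count = as.integer(counts), percent = pct(as.integer(counts), total))
  }
  age_band <- dplyr::case_when(
    is.na(reports$age_years) ~ NA_character_,
    reports$age_years < 18 ~ "<18",
    reports$age_years < 60 ~ "18-60",
    TRUE ~ ">=60"
  )
  dplyr::bind_rows(
    tab_one("sex", reports$sex, c("F", "M", "OTHER", "NA")),
    tab_one("age", age_band, c("<18", "18-60", ">=60", "NA")),
    tab_one("occupation", reports$occupation,
            c("CONSUMER", "HEALTH_PROFESSIONAL", "OTHER", "NA"))
  )
}

#' Report counts by receipt year
#'
#' Counts reports per calendar year of the receipt date, filling years with
#' no reports inside the observed range with zero. Reports without a date are
#' tallied under the `NA` year. Counts sum to the dataset total.
#'
#' @param reports Report tibble.
#' @return Tibble with columns `year` (integer, `NA` for undated) and
#'   `count`.
#' @export
counts_by_year <- function(reports) {
  stopifnot_reports(reports)
  if (nrow(reports) == 0) return(tibble(year = integer(), count = integer()))
  year <- lubridate::year(reports$receipt_date)
  obs <- year[!is.na(year)]
  out <- tibble(year = integer(), count = integer())
  if (length(obs)) {
    span <- seq(min(obs), max(obs))
    counts <- table(factor(obs, levels = span))
    out <- tibble(year = span, count = as.integer(counts))
  }
  if (anyNA(year)) {
    out <- dplyr::bind_rows(out, tibble(year = NA_integer_,
                                        count = sum(is.na(year))))
  }
  out
}

#' Reporting-country ranking
#'
#' Counts reports per reporter country, most frequent first; missing
#' countries are tallied under `"NA"`.
#'
#' @param reports Report tibble.
#' @param top_n Keep the `top_n` most frequent countries (default all).
#' @return Tibble with columns `country`, `count`, `percent`.
#' @export
count_countries <- function(reports, top_n = Inf) {
  stopifnot_reports(reports)
  total <- nrow(reports)
  out <- tibble(country = na_label(reports$country)) |>
    dplyr::count(.data$country, name = "count", sort = TRUE) |>
    dplyr::mutate(percent = pct(.data$count, total))
  if (is.finite(top_n)) out <- dplyr::slice_head(out, n = as.integer(top_n))
  out
}

#' Distribution of the most severe outcome
#'
#' Reduces every report to its single most severe outcome code (see
#' [most_severe_outcome()]) and tabulates the result; reports without any
#' outcome flag fall in the `NA` stratum. Counts sum to the dataset total.
#'
#' @param reports Report tibble.
#' @return Tibble with columns `outcome` (ordered `DE` to `OT`, then `NA`),
#'   `count`, `percent`.
#' @export
outcome_distribution <- function(reports) {
  stopifnot_reports(reports)
  total <- nrow(reports)
  worst <- vapply(reports$outcomes, most_severe_outcome, "")
  levels <- c(outcome_severity, "NA")
  counts <- table(factor(na_label(worst), levels = levels))
  tibble(outcome = levels, count = as.integer(counts),
         percent = pct(as.integer(counts), total))
}
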