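#' Delimited-file dialects for report tables
#'
#' A dialect bundles the delimiter and quoting convention of a report file.
#' Three presets cover the common cases: `"csv"` (comma, double-quote),
#' `"tsv"` (tab), and `"faers_ascii"` (dollar-delimited, the convention of the
#' raw FAERS quarterly ASCII extracts; provided as a delimiter preset only,
#' not a guarantee of full FAERS schema coverage).
#'
#' @param delim Single-character field delimiter.
#' @param quote Quoting character (`'"'` or `""` for none).
#' @return A list with elements `delim` and `quote`, class `"pv_dialect"`.
#' @examples
#' report_dialect("csv")
#' report_dialect(delim = ";")
#' @export
report_dialect <- function(delim = ",", quote = "\"") {
  if (length(delim) == 1 && delim %in% c("csv", "tsv", "faers_ascii")) {
    delim <- switch(delim, csv = ",", tsv = "\t", faers_ascii = "$")
  }
  stopifnot(is.character(delim), nchar(delim) == 1L)
  structure(list(delim = delim, quote = quote), class = "pv_dialect")
}

as_dialect <- function(dialect) {
  if (inherits(dialect, "pv_dialect")) dialect else report_dialect(dialect)
}

# The on-disk long schema: one row per report x drug/reaction slot.
report_file_columns <- c(
  "report_id", "case_id", "receipt_date", "age_years", "sex", "occupation",
  "country", "drug_verbatim", "drug_standardized", "is_combination",
  "reaction_pt", "outcome_codes"
)

empty_reports <- function() {
  tibble(
    report_id = character(), case_id = character(),
    receipt_date = as.Date(character()), age_years = numeric(),
    sex = character(), occupation = character(), country = character(),
    drug_verbatim = list(), drug_standardized = list(),
    drug_combination = list(), reactions = list(), outcomes = list()
  )
}

#' Read spontaneous reports from a delimited file
#'
#' Reads a long-format report table (one row per report x drug/reaction slot)
#' and assembles one record per report: rows sharing a `report_id` are merged,
#' with drugs, reactions and outcome codes accumulated. The long schema has
#' columns `report_id, case_id, receipt_date, age_years, sex, occupation,
#' country, drug_verbatim, drug_standardized, is_combination, reaction_pt,
#' outcome_codes`; empty strings are missing values. This mirrors the FAERS
#' DEMO/DRUG/REAC/OUTC split without requiring four files.
#'
#' Malformed rows (empty `report_id`) are counted and dropped with a message,
#' never silently. Unparseable dates and out-of-range ages (outside 0-150) are
#' set to missing and counted. The counts are attached as the
#' `"read_problems"` attribute.
#'
#' @param path Path to the delimited file.
#' @param dialect A [report_dialect()], or one of `"csv"`, `"tsv"`,
#'   `"faers_ascii"`.
#' @return A tibble with one row per report: identifier and demographic
#'   columns plus list-columns `drug_verbatim`, `drug_standardized`,
#'   `drug_combination` (parallel per drug entry), `reactions` (MedDRA PT
#'   strings) and `outcomes` (outcome codes).
#' @seealso [write_reports()] for the inverse; the two round-trip exactly.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' reports <- generate_reports(synthetic_config(n_reports = 50, seed = 1))
#' write_reports(reports, path)
#' reread <- read_reports(path)
#' identical(reread$report_id, reports$report_id)
#' @export
read_reports <- function(path, dialect = "csv") {
  d <- as_dialect(dialect)
  raw <- readr::read_delim(
    path, delim = d$delim, quote = d$quote, na = character(),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(report_file_columns, names(raw))
  if (length(missing_cols)) {
    stop("report file lacks mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[report_file_columns]

  n_malformed <- sum(raw$report_id == "" | is.na(raw$report_id))
  if (n_malformed > 0) {
    message(n_malformed, " malformed row(s) without a report_id dropped")
    raw <- raw[!(raw$report_id == "" | is.na(raw$report_id)), ]
  }
  if (nrow(raw) == 0) {
    out <- empty_reports()
    attr(out, "read_problems") <-
      c(malformed_rows = n_malformed, bad_dates = 0L, bad_ages = 0L)
    return(out)
  }

  blank_to_na <- function(x) ifelse(x == "", NA_character_, x)

  # merge row-groups in first-appearance order
  grp <- factor(raw$report_id, levels = unique(raw$report_id))
  idx_first <- !duplicated(grp)
  first <- raw[idx_first, ]

  date_chr <- blank_to_na(first$receipt_date)
  dates <- suppressWarnings(lubridate::ymd(date_chr, quiet = TRUE))
  n_bad_dates <- sum(!is.na(date_chr) & is.na(dates))

  age <- suppressWarnings(as.numeric(blank_to_na(first$age_years)))
  bad_age <- !is.na(age) & (age < 0 | age > 150)
  n_bad_ages <- sum(bad_age) +
    sum(!is.na(blank_to_na(first$age_years)) & is.na(age))
  age[bad_age] <- NA_real_

  has_drug_row <- raw$drug_verbatim != ""
  split_by <- function(x, keep) {
    unname(split(x[keep], factor(raw$report_id[keep], levels = levels(grp))))
  }
  drug_verbatim <- split_by(raw$drug_verbatim, has_drug_row)
  drug_standardized <- split_by(blank_to_na(raw$drug_standardized), has_drug_row)
  drug_combination <- split_by(
    raw$is_combination %in% c("TRUE", "true", "1"), has_drug_row
  )
  # unresolved entries carry NA for the combination flag too
  drug_combination <- purrr::map2(
    drug_combination, drug_standardized,
    function(fl, st) ifelse(is.na(st), NA, fl)
  )
  reactions <- split_by(raw$reaction_pt, raw$reaction_pt != "")

  outc <- raw$outcome_codes[raw$outcome_codes != ""]
  outc_grp <- grp[raw$outcome_codes != ""]
  outcomes <- rep(list(character()), nlevels(grp))
  if (length(outc)) {
    keep <- !duplicated(outc_grp)  # codes live on the first row of a report
    outcomes[as.integer(outc_grp[keep])] <- strsplit(outc[keep], "|", fixed = TRUE)
  }

  out <- tibble(
    report_id = first$report_id,
    case_id = blank_to_na(first$case_id),
    receipt_date = dates,
    age_years = age,
    sex = blank_to_na(first$sex),
    occupation = blank_to_na(first$occupation),
    country = blank_to_na(first$country),
    drug_verbatim = drug_verbatim,
    drug_standardized = drug_standardized,
    drug_combination = drug_combination,
    reactions = reactions,
    outcomes = outcomes
  )
  attr(out, "read_problems") <- c(
    malformed_rows = n_malformed, bad_dates = n_bad_dates, bad_ages = n_bad_ages
  )
  out
}

#' Write spontaneous reports to a delimited file
#'
#' Serializes a report table to the long format documented in
#' [read_reports()]. A report with `k` drugs and `m` reactions occupies
#' `max(k, m)` rows; drug and reaction slots beyond their own count are left
#' empty, outcome codes are `|`-joined on the report's first row, and missing
#' values are written as empty strings. `read_reports(write_reports(x))`
#' reproduces `x` field for field.
#'
#' @param reports A report tibble as returned by [read_reports()] or
#'   [generate_reports()].
#' @param path Output file path.
#' @param dialect A [report_dialect()] or preset name.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path, dialect = "csv") {
  stopifnot_reports(reports)
  d <- as_dialect(dialect)
  if (nrow(reports) == 0) {
    long <- as_tibble(setNames(
      as.list(rep(list(character()), length(report_file_columns))),
      report_file_columns
    ))
  } else {
    n_drug <- lengths(reports$drug_verbatim)
    n_reac <- lengths(reports$reactions)
    n_rows <- pmax(n_drug, n_reac, 1L)
    rep_idx <- rep.int(seq_len(nrow(reports)), n_rows)
    slot <- sequence(n_rows)

    pick <- function(lst, lens, chr = TRUE) {
      flat <- unlist(lst, use.names = FALSE)
      if (is.null(flat)) flat <- if (chr) character() else logical()
      offset <- cumsum(c(0L, lens[-length(lens)]))
      pos <- ifelse(slot <= lens[rep_idx], offset[rep_idx] + slot, NA_integer_)
      flat[pos]
    }
    blank <- function(x) ifelse(is.na(x), "", as.character(x))

    long <- tibble(
      report_id = reports$report_id[rep_idx],
      case_id = blank(reports$case_id[rep_idx]),
      receipt_date = blank(format(reports$receipt_date[rep_idx], "%Y-%m-%d")),
      age_years = blank(reports$age_years[rep_idx]),
      sex = blank(reports$sex[rep_idx]),
      occupation = blank(reports$occupation[rep_idx]),
      country = blank(reports$country[rep_idx]),
      drug_verbatim = blank(pick(reports$drug_verbatim, n_drug)),
      drug_standardized = blank(pick(reports$drug_standardized, n_drug)),
      is_combination = blank(pick(reports$drug_combination, n_drug, chr = FALSE)),
      reaction_pt = blank(pick(reports$reactions, n_reac)),
      outcome_codes = ifelse(
        slot == 1L,
        vapply(reports$outcomes[rep_idx], paste, "", collapse = "|"),
        ""
      )
    )
  }
  readr::write_delim(long, path, delim = d$delim, na = "", progress = FALSE)
  invisible(path)
}
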