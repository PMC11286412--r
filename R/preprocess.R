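#' Outcome codes in decreasing order of severity
#'
#' The seven FAERS seriousness flags: death (DE), life-threatening (LT),
#' hospitalization (HO), disability (DS), congenital anomaly (CA),
#' required intervention (RI), other (OT). The vector is ordered from most to
#' least severe; this conventional hierarchy (death worst) drives
#' [most_severe_outcome()].
#'
#' @format Character vector of length 7.
#' @export
outcome_severity <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Build or read a drug-synonym map
#'
#' A synonym map resolves verbatim drug names (as reported) to standardized
#' generic names via exact, case-insensitive lookup, and flags which
#' standardized names denote combination products (formulations with more
#' than one active ingredient, kept as a single drug entity). The file form is
#' a CSV with columns `verbatim, standardized` and an optional logical
#' `is_combination`.
#'
#' @param verbatim Character vector of verbatim names (case-folded on entry).
#' @param standardized Character vector of standardized generic names,
#'   parallel to `verbatim`; empty names are not allowed.
#' @param combinations Character vector of standardized names that are
#'   combination products.
#' @return A `synonym_map` object.
#' @examples
#' synonym_map(
#'   verbatim = c("LISINOPRIL 10MG TAB", "amoxicillin/clavulanate"),
#'   standardized = c("lisinopril", "amoxicillin potassium clavulanate combination"),
#'   combinations = "amoxicillin potassium clavulanate combination"
#' )
#' @export
synonym_map <- function(verbatim = character(), standardized = character(),
                        combinations = character()) {
  stopifnot(length(verbatim) == length(standardized))
  if (any(is.na(standardized) | standardized == "")) {
    stop("standardized names must be non-empty", call. = FALSE)
  }
  keys <- normalize_label(verbatim)
  if (anyDuplicated(keys)) {
    stop("duplicate verbatim names after case-folding: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  }
  structure(
    list(entries = setNames(normalize_label(standardized), keys),
         combinations = normalize_label(combinations)),
    class = "synonym_map"
  )
}

#' @rdname synonym_map
#' @param path CSV file with columns `verbatim, standardized`
#'   and optionally `is_combination`.
#' @export
read_synonym_map <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (!all(c("verbatim", "standardized") %in% names(tab))) {
    stop("synonym map needs columns: verbatim, standardized", call. = FALSE)
  }
  comb <- if ("is_combination" %in% names(tab)) {
    tab$standardized[tab$is_combination %in% c("TRUE", "true", "1")]
  } else {
    character()
  }
  synonym_map(tab$verbatim, tab$standardized, comb)
}

#' Standardize drug names against a synonym map
#'
#' Resolves each drug entry's verbatim name by exact case-insensitive lookup.
#' Resolved entries get the standardized generic name and the combination
#' flag from the map; unresolved entries keep their verbatim form (missing
#' standardized name, missing flag) and are retained, never dropped.
#' Combination products keep a single combined identity and are not split
#' into components.
#'
#' @param reports Report tibble.
#' @param map A [synonym_map()].
#' @return The report tibble with `drug_standardized` and `drug_combination`
#'   filled in where the lookup succeeded.
#' @export
standardize_drugs <- function(reports, map) {
  stopifnot_reports(reports)
  stopifnot(inherits(map, "synonym_map"))
  if (length(map$entries) == 0) {
    warning("empty synonym map: all drug names left unresolved", call. = FALSE)
  }
  lens <- lengths(reports$drug_verbatim)
  flat <- normalize_label(unlist(reports$drug_verbatim, use.names = FALSE))
  std <- unname(map$entries[flat])
  comb <- ifelse(is.na(std), NA, std %in% map$combinations)
  reports$drug_standardized <- chop_by(std, lens)
  reports$drug_combination <- chop_by(comb, lens)
  reports
}

#' Remove duplicate reports and retain the latest event per case
#'
#' Two cleaning rules for spontaneous-report data:
#' \enumerate{
#' \item Reports identical on (case identifier, receipt date, set of
#'   standardized drug names) are duplicates; exactly one survives.
#' \item Among several reports of the same case for the same medication
#'   profile across different dates, only the latest is retained.
#' }
#' Missing case identifiers and dates take part as their own sentinel value
#' (two missing dates compare equal); a missing date sorts earliest, so dated
#' evidence is preferred. Ties are broken by keeping the lexicographically
#' greatest `report_id`, which makes the result independent of input order.
#' The operation is idempotent.
#'
#' @param reports Report tibble (standardized names are used for the drug-set
#'   key where available, verbatim otherwise).
#' @return The deduplicated tibble, with attribute `"n_removed"` giving the
#'   number of dropped reports.
#' @export
deduplicate <- function(reports) {
  stopifnot_reports(reports)
  n_in <- nrow(reports)
  if (n_in == 0) {
    attr(reports, "n_removed") <- 0L
    return(reports)
  }
  drug_key <- vapply(
    drug_name_sets(reports),
    function(d) paste(sort(unique(d)), collapse = "\x1f"), ""
  )
  case_key <- ifelse(is.na(reports$case_id), "\x1dNA", reports$case_id)
  date_key <- ifelse(is.na(reports$receipt_date), "\x1dNA",
                     format(reports$receipt_date, "%Y-%m-%d"))
  # missing dates sort before any real date
  date_ord <- ifelse(is.na(reports$receipt_date), -Inf,
                     as.numeric(reports$receipt_date))

  keep <- tibble(
    i = seq_len(n_in), case_key = case_key, date_key = date_key,
    drug_key = drug_key, date_ord = date_ord, report_id = reports$report_id
  ) |>
    # rule 1: exact duplicates collapse to the greatest report_id
    dplyr::group_by(.data$case_key, .data$date_key, .data$drug_key) |>
    dplyr::slice_max(.data$report_id, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    # rule 2: latest date per (case, drug set)
    dplyr::group_by(.data$case_key, .data$drug_key) |>
    dplyr::arrange(dplyr::desc(.data$date_ord), dplyr::desc(.data$report_id),
                   .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup()

  out <- reports[sort(keep$i), ]
  attr(out, "n_removed") <- n_in - nrow(out)
  out
}

#' Drop excluded drugs and the reports left empty
#'
#' Removes drug entries whose standardized name (verbatim when unresolved)
#' appears on the exclusion list — e.g. non-pharmaceutical products or drugs
#' withdrawn from the market. Reports left with no drug entry are dropped and
#' counted.
#'
#' @param reports Report tibble.
#' @param exclusions Character vector of standardized names to exclude, or a
#'   path to a one-column CSV (column `standardized`).
#' @return Filtered report tibble with attributes `"n_drugs_removed"` and
#'   `"n_reports_removed"`.
#' @export
exclude_drugs <- function(reports, exclusions) {
  stopifnot_reports(reports)
  if (length(exclusions) == 1 && is.character(exclusions) &&
      file.exists(exclusions)) {
    tab <- readr::read_csv(exclusions, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
    exclusions <- tab[[1]]
  }
  exclusions <- normalize_label(exclusions)
  if (length(exclusions) == 0 || nrow(reports) == 0) {
    attr(reports, "n_drugs_removed") <- 0L
    attr(reports, "n_reports_removed") <- 0L
    return(reports)
  }
  names_by_report <- drug_name_sets(reports)
  keep_entry <- purrr::map(names_by_report, function(d) !(d %in% exclusions))
  n_drugs_removed <- sum(lengths(names_by_report)) - sum(unlist(keep_entry))
  reports$drug_verbatim <- purrr::map2(reports$drug_verbatim, keep_entry, `[`)
  reports$drug_standardized <- purrr::map2(reports$drug_standardized, keep_entry, `[`)
  reports$drug_combination <- purrr::map2(reports$drug_combination, keep_entry, `[`)
  empty <- lengths(reports$drug_verbatim) == 0L
  out <- reports[!empty, ]
  attr(out, "n_drugs_removed") <- n_drugs_removed
  attr(out, "n_reports_removed") <- sum(empty)
  out
}

#' Match reports against a MedDRA preferred term
#'
#' TRUE for every report whose reaction list contains the target PT after
#' case-folding and whitespace normalization. Matching is exact on the PT
#' string — no SMQ expansion, so e.g. "Angioedema hereditary" does not match
#' the PT "angioedema". Invariant to reaction order and letter case.
#'
#' @param reports Report tibble.
#' @param pt Non-empty MedDRA preferred term, e.g. `"Angioedema"`.
#' @return Logical vector, one element per report.
#' @export
match_event <- function(reports, pt) {
  stopifnot_reports(reports)
  stopifnot(is.character(pt), length(pt) == 1L, !is.na(pt), nzchar(pt))
  lens <- lengths(reports$reactions)
  flat <- normalize_label(unlist(reports$reactions, use.names = FALSE))
  out <- logical(nrow(reports))
  hit <- flat == normalize_label(pt)
  if (any(hit)) {
    grp <- rep.int(seq_len(nrow(reports)), lens)
    out[unique(grp[hit])] <- TRUE
  }
  out
}

#' Most severe outcome of a report
#'
#' Reduces a vector of outcome codes to the single most severe one under the
#' fixed ordering `DE > LT > HO > DS > CA > RI > OT` (see
#' [outcome_severity]). FAERS reports may carry several outcome flags; when a
#' single final outcome is needed the most severe is selected.
#'
#' @param codes Character vector of outcome codes (possibly empty).
#' @return A single code, or `NA` for an empty vector.
#' @examples
#' most_severe_outcome(c("HO", "DE"))  # "DE"
#' most_severe_outcome(character())    # NA
#' @export
most_severe_outcome <- function(codes) {
  idx <- match(codes, outcome_severity)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) NA_character_ else outcome_severity[min(idx)]
}

#' Clean a report table end to end
#'
#' Runs the standard cleaning pipeline: drug-name standardization (when a
#' synonym map is supplied), duplicate removal with latest-event retention,
#' drug exclusions, and finally the count of reports matching the target
#' event PT. Standardization runs first so that duplicate keys compare
#' standardized names.
#'
#' @param reports Report tibble.
#' @param map Optional [synonym_map()].
#' @param exclusions Optional exclusion list (vector or file path).
#' @param event_pt Optional target PT; when given, `n_event_matched` is
#'   reported.
#' @return The cleaned tibble, with a `"cleaning_report"` attribute (see
#'   [cleaning_report()]).
#' @export
clean_reports <- function(reports, map = NULL, exclusions = NULL,
                          event_pt = NULL) {
  stopifnot_reports(reports)
  n_input <- nrow(reports)
  if (!is.null(map)) reports <- standardize_drugs(reports, map)
  reports <- deduplicate(reports)
  n_after_dedup <- nrow(reports)
  if (!is.null(exclusions)) reports <- exclude_drugs(reports, exclusions)
  n_after_exclusion <- nrow(reports)
  n_event <- if (is.null(event_pt)) NA_integer_ else sum(match_event(reports, event_pt))
  attr(reports, "cleaning_report") <- tibble(
    n_input = n_input,
    n_after_dedup = n_after_dedup,
    n_after_exclusion = n_after_exclusion,
    n_event_matched = n_event
  )
  reports
}

#' Retrieve the cleaning report of a cleaned table
#'
#' @param reports A tibble returned by [clean_reports()].
#' @return One-row tibble with columns `n_input`, `n_after_dedup`,
#'   `n_after_exclusion`, `n_event_matched` (monotone non-increasing along
#'   the pipeline).
#' @export
cleaning_report <- function(reports) {
  rep <- attr(reports, "cleaning_report")
  if (is.null(rep)) stop("no cleaning report attached; run clean_reports()",
                         call. = FALSE)
  rep
}
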