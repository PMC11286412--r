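#' Read a drug-to-category map
#'
#' A category map assigns each standardized drug name to exactly one
#' therapeutic category (by physiological system and pharmacological
#' mechanism, e.g. "cardiovascular drugs", "antithrombotic agents"). The file
#' form is a two-column CSV `drug, category`.
#'
#' A best-effort map covering 30 frequently reported drugs in 10 categories
#' ships with the package:
#' `system.file("extdata", "drug_categories.csv", package = "pvsignal")`.
#'
#' @param path CSV file with columns `drug, category`.
#' @return Tibble with columns `drug` (normalized) and `category`.
#' @export
read_category_map <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (!all(c("drug", "category") %in% names(tab))) {
    stop("category map needs columns: drug, category", call. = FALSE)
  }
  if (any(is.na(tab$category) | tab$category == "")) {
    stop("category labels must be non-empty", call. = FALSE)
  }
  tab$drug <- normalize_label(tab$drug)
  if (anyDuplicated(tab$drug)) {
    stop("each drug must map to exactly one category; duplicated: ",
         paste(unique(tab$drug[duplicated(tab$drug)]), collapse = ", "),
         call. = FALSE)
  }
  tibble(drug = tab$drug, category = tab$category)
}

#' Category-level disproportionality rollup
#'
#' Rolls individual drugs up into therapeutic categories and computes the
#' four-fold table and ROR/PRR statistics per category. Counting stays at
#' report level: a report with two drugs of the same category counts once in
#' that category's exposed cells, while a report spanning several categories
#' contributes to each. Drugs absent from the map are pooled under
#' `"unclassified"` with a warning.
#'
#' @param reports Cleaned report tibble.
#' @param category_map Tibble with columns `drug, category` (see
#'   [read_category_map()]).
#' @param event Target MedDRA PT (default `"Angioedema"`).
#' @param min_reports Minimum `a` for a signal (default 3).
#' @param zero_cell Zero-cell policy passed to [compute_ror()].
#' @return A `pv_screen` tibble, one row per category (same columns as
#'   [screen_drugs()], with `category` in place of `drug`).
#' @export
rollup_categories <- function(reports, category_map, event = "Angioedema",
                              min_reports = 3,
                              zero_cell = c("none", "haldane")) {
  stopifnot_reports(reports)
  zero_cell <- match.arg(zero_cell)
  stopifnot(all(c("drug", "category") %in% names(category_map)))
  lookup <- setNames(category_map$category, normalize_label(category_map$drug))

  name_sets <- drug_name_sets(reports)
  flat <- unlist(name_sets, use.names = FALSE)
  cats <- unname(lookup[flat])
  n_unmapped <- sum(is.na(cats))
  if (n_unmapped > 0) {
    warning(n_unmapped, " drug entr(ies) not in the category map counted as ",
            "'unclassified'", call. = FALSE)
    cats[is.na(cats)] <- "unclassified"
  }
  cat_sets <- chop_by(cats, lengths(name_sets))

  out <- group_tables(reports, cat_sets, event) |>
    dplyr::rename(category = "group") |>
    dplyr::arrange(dplyr::desc(.data$a), .data$category) |>
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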