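write_result_csv <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_csv(x, path, na = "", progress = FALSE)
  path
}

resolve_reports <- function(reports, dialect) {
  if (is.character(reports)) {
    if (!file.exists(reports)) stop("report file not found: ", reports,
                                    call. = FALSE)
    reports <- read_reports(reports, dialect)
  }
  stopifnot_reports(reports)
  reports
}

#' Run the full screening pipeline and write its artifacts
#'
#' Cleans the reports (standardize when a synonym map is given, deduplicate,
#' exclude), screens every drug against the target event, rolls drugs up
#' into categories when a category map is given, and writes
#' `drug_screen.csv`, `category_screen.csv` (if applicable),
#' `cleaning_report.csv` and a deterministic `run_log.txt` to `out_dir`.
#' Outputs are byte-identical across runs on identical inputs.
#'
#' @param reports Report tibble or path to a report file.
#' @param out_dir Output directory (created if needed).
#' @param synonym_map Optional [synonym_map()] or path to one.
#' @param category_map Optional category-map tibble or path
#'   (see [read_category_map()]).
#' @param exclusions Optional exclusion vector or path.
#' @param event Target MedDRA PT (default `"Angioedema"`).
#' @param min_reports,top_n,zero_cell Screening thresholds, see
#'   [screen_drugs()]. Defaults: at least 3 target reports, top 30 drugs.
#' @param dialect Input file dialect (see [report_dialect()]).
#' @return Invisibly, a list with elements `drugs`, `categories` (or `NULL`),
#'   `cleaning`, and `files` (paths written).
#' @export
run_screen <- function(reports, out_dir, synonym_map = NULL,
                       category_map = NULL, exclusions = NULL,
                       event = "Angioedema", min_reports = 3, top_n = 30,
                       zero_cell = c("none", "haldane"), dialect = "csv") {
  zero_cell <- match.arg(zero_cell)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- resolve_reports(reports, dialect)
  if (is.character(synonym_map)) synonym_map <- read_synonym_map(synonym_map)
  if (is.character(category_map)) category_map <- read_category_map(category_map)

  cleaned <- clean_reports(reports, map = synonym_map,
                           exclusions = exclusions, event_pt = event)
  cleaning <- cleaning_report(cleaned)
  drugs <- screen_drugs(cleaned, event = event, min_reports = min_reports,
                        top_n = top_n, zero_cell = zero_cell)
  files <- c(
    write_result_csv(tidy(drugs), out_dir, "drug_screen.csv"),
    write_result_csv(cleaning, out_dir, "cleaning_report.csv")
  )
  categories <- NULL
  if (!is.null(category_map)) {
    categories <- rollup_categories(cleaned, category_map, event = event,
                                    min_reports = min_reports,
                                    zero_cell = zero_cell)
    files <- c(files,
               write_result_csv(tidy(categories), out_dir,
                                "category_screen.csv"))
  }

  cfg <- list(event = event, min_reports = min_reports, top_n = top_n,
              zero_cell = zero_cell)
  log_lines <- c(
    paste0("pvsignal ", as.character(utils::packageVersion("pvsignal"))),
    paste0("config_hash ", rlang::hash(cfg)),
    paste0("n_input ", cleaning$n_input),
    paste0("n_after_dedup ", cleaning$n_after_dedup),
    paste0("n_after_exclusion ", cleaning$n_after_exclusion),
    paste0("n_event_matched ", cleaning$n_event_matched),
    paste0("n_drugs_screened ", nrow(drugs)),
    paste0("n_signals ", sum(drugs$signal, na.rm = TRUE))
  )
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  files <- c(files, log_path)
  invisible(list(drugs = drugs, categories = categories, cleaning = cleaning,
                 files = files))
}

#' Write the descriptive summaries of a report set
#'
#' Writes `demographics.csv`, `yearly_counts.csv`, `outcomes.csv` and
#' `countries.csv` to `out_dir`.
#'
#' @inheritParams run_screen
#' @return Invisibly, a list of the four summary tibbles plus `files`.
#' @export
run_describe <- function(reports, out_dir, dialect = "csv") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- resolve_reports(reports, dialect)
  demo <- summarize_demographics(reports)
  years <- counts_by_year(reports)
  outcomes <- outcome_distribution(reports)
  countries <- count_countries(reports)
  files <- c(
    write_result_csv(demo, out_dir, "demographics.csv"),
    write_result_csv(years, out_dir, "yearly_counts.csv"),
    write_result_csv(outcomes, out_dir, "outcomes.csv"),
    write_result_csv(countries, out_dir, "countries.csv")
  )
  invisible(list(demographics = demo, yearly = years, outcomes = outcomes,
                 countries = countries, files = files))
}

#' Generate and write a synthetic dataset with its ground truth
#'
#' Writes the generated reports (via [write_reports()]) and a ground-truth
#' sidecar CSV of each catalog drug's true odds ratio.
#'
#' @param config A [synthetic_config()].
#' @param out_path Path for the report file.
#' @param truth_path Path for the truth sidecar (default: `out_path` with a
#'   `_truth.csv` suffix).
#' @param dialect Output dialect.
#' @return Invisibly, the generated report tibble.
#' @export
run_simulate <- function(config, out_path,
                         truth_path = sub("(\\.[^.]+)?$", "_truth.csv",
                                          out_path),
                         dialect = "csv") {
  stopifnot(inherits(config, "synthetic_config"))
  reports <- generate_reports(config)
  write_reports(reports, out_path, dialect)
  readr::write_csv(attr(reports, "truth"), truth_path, progress = FALSE)
  invisible(reports)
}
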