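default_drug_catalog <- function() {
  tibble(
    name = c(
      "lisinopril", "enalapril", "perindopril", "ramipril", "losartan",
      "valsartan", "amlodipine", "hydrochlorothiazide and lisinopril",
      "alteplase", "carbasalate calcium", "ibuprofen", "naproxen",
      "paracetamol", "diclofenac", "celecoxib", "pregabalin", "amoxicillin",
      "amoxicillin potassium clavulanate combination", "clarithromycin",
      "lansoprazole", "omeprazole", "infliximab", "secukinumab", "etanercept",
      "adalimumab", "lenalidomide", "sitagliptin phosphate", "cetirizine",
      "omalizumab", "montelukast"
    ),
    p = c(
      0.030, 0.012, 0.006, 0.015, 0.025,
      0.020, 0.035, 0.008,
      0.006, 0.003, 0.040, 0.020,
      0.050, 0.018, 0.012, 0.020, 0.030,
      0.015, 0.010,
      0.015, 0.030, 0.012, 0.008, 0.015,
      0.025, 0.012, 0.012, 0.015,
      0.006, 0.015
    ),
    is_combination = c(
      FALSE, FALSE, FALSE, FALSE, FALSE,
      FALSE, FALSE, TRUE,
      FALSE, FALSE, FALSE, FALSE,
      FALSE, FALSE, FALSE, FALSE, FALSE,
      TRUE, FALSE,
      FALSE, FALSE, FALSE, FALSE, FALSE,
      FALSE, FALSE, FALSE, FALSE,
      FALSE, FALSE
    )
  )
}

# Non-target reaction PTs used as background noise.
noise_pts <- c(
  "Rash", "Nausea", "Headache", "Dizziness", "Pruritus", "Fatigue",
  "Dyspnoea", "Vomiting", "Diarrhoea", "Drug ineffective"
)

norm_marginal <- function(x, what) {
  if (is.null(names(x)) || any(!is.finite(x)) || any(x < 0) || sum(x) <= 0) {
    stop("invalid ", what, ": need a named nonnegative vector with mass",
         call. = FALSE)
  }
  x / sum(x)
}

#' Configuration for the synthetic spontaneous-report generator
#'
#' Bundles and validates every knob of [generate_reports()]. Defaults emulate
#' a spontaneous-report stream for an angioedema screen: a 30-drug catalog
#' with per-drug reporting marginals, demographic marginals resembling a
#' large FAERS angioedema cohort (sex roughly 47/44% F/M with 8% missing;
#' three age bands with about a fifth missing; reporters dominated by health
#' professionals), receipt years uniform over 2004-2023, and a null event
#' model (all true odds ratios 1).
#'
#' The event model is logistic per report: the event odds are
#' `background_event_rate / (1 - background_event_rate)` multiplied by the
#' true odds ratio `theta` of every exposed signal drug. For a drug that is
#' the only one with `theta != 1` the population reporting odds ratio equals
#' its configured `theta` exactly; with several independent signal drugs the
#' marginal odds ratios deviate only by the (negligible at these marginals)
#' non-collapsibility of the odds ratio.
#'
#' @param n_reports Number of primary reports (before duplicate injection).
#' @param drug_catalog Tibble with columns `name`, `p` (marginal reporting
#'   probability per report) and optionally `is_combination`.
#' @param event_pt Target event preferred term (default `"Angioedema"`).
#' @param background_event_rate Event probability for a report exposed to no
#'   signal drug (default 0.02).
#' @param drug_event_or Named vector of true odds ratios, e.g.
#'   `c(lisinopril = 20)`; drugs not named have `theta = 1`.
#' @param mean_drugs_per_report Optional target for the expected number of
#'   drug entries per report; when given, catalog marginals are rescaled
#'   proportionally. At least one drug per report is enforced by redrawing.
#' @param dup_rate Fraction of primary reports duplicated (exact copies with
#'   a fresh report identifier, same case/date/drugs); default 0.10.
#' @param sex_marginal,age_marginal,occupation_marginal,country_marginal,outcome_mixture
#'   Named probability vectors (normalized internally). `age_marginal` is
#'   over the bands `<18`, `18-60`, `>=60`, `NA`; `outcome_mixture` includes
#'   a `NONE` mass for reports without outcome flags.
#' @param year_range Integer vector of receipt years, sampled uniformly.
#' @param seed Integer seed; identical configurations generate bit-identical
#'   datasets.
#' @return A validated `synthetic_config` object.
#' @examples
#' synthetic_config(n_reports = 1000, seed = 7,
#'                  drug_event_or = c(lisinopril = 20))
#' @export
synthetic_config <- function(n_reports,
                             drug_catalog = default_drug_catalog(),
                             event_pt = "Angioedema",
                             background_event_rate = 0.02,
                             drug_event_or = NULL,
                             mean_drugs_per_report = NULL,
                             dup_rate = 0.10,
                             sex_marginal = c(F = 0.469, M = 0.440,
                                              OTHER = 0.008, "NA" = 0.083),
                             age_marginal = c("<18" = 0.049, "18-60" = 0.376,
                                              ">=60" = 0.362, "NA" = 0.213),
                             occupation_marginal = c(
                               CONSUMER = 0.138, HEALTH_PROFESSIONAL = 0.728,
                               OTHER = 0.093, "NA" = 0.041),
                             country_marginal = c(
                               US = 0.56, FR = 0.07, GB = 0.05, CA = 0.04,
                               IT = 0.03, DE = 0.03, ES = 0.02, PT = 0.02,
                               JP = 0.02, BR = 0.02, NL = 0.02, AU = 0.02,
                               CN = 0.005, OTHER = 0.059, "NA" = 0.036),
                             outcome_mixture = c(
                               HO = 0.300, DE = 0.100, LT = 0.060, DS = 0.030,
                               CA = 0.002, RI = 0.010, OT = 0.380,
                               NONE = 0.118),
                             year_range = 2004:2023,
                             seed = 1L) {
  stopifnot(is.numeric(n_reports), length(n_reports) == 1L, n_reports >= 1)
  stopifnot(all(c("name", "p") %in% names(drug_catalog)),
            nrow(drug_catalog) >= 1)
  if (!"is_combination" %in% names(drug_catalog)) {
    drug_catalog$is_combination <- FALSE
  }
  drug_catalog$name <- normalize_label(drug_catalog$name)
  if (anyDuplicated(drug_catalog$name)) {
    stop("duplicate drug names in catalog", call. = FALSE)
  }
  if (any(drug_catalog$p < 0 | drug_catalog$p > 1) ||
      sum(drug_catalog$p) <= 0) {
    stop("catalog marginals must be probabilities with positive mass",
         call. = FALSE)
  }
  if (!is.null(mean_drugs_per_report)) {
    stopifnot(mean_drugs_per_report > 0)
    scale <- mean_drugs_per_report / sum(drug_catalog$p)
    drug_catalog$p <- pmin(drug_catalog$p * scale, 1)
  }
  stopifnot(background_event_rate > 0, background_event_rate < 1)
  theta <- setNames(rep(1, nrow(drug_catalog)), drug_catalog$name)
  if (!is.null(drug_event_or)) {
    unknown <- setdiff(names(drug_event_or), drug_catalog$name)
    if (length(unknown)) {
      stop("drug_event_or names not in catalog: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(drug_event_or <= 0)) stop("odds ratios must be positive",
                                      call. = FALSE)
    theta[names(drug_event_or)] <- drug_event_or
  }
  stopifnot(dup_rate >= 0, dup_rate <= 1)
  stopifnot(is.numeric(year_range), length(year_range) >= 1)
  structure(list(
    n_reports = as.integer(n_reports),
    drug_catalog = drug_catalog,
    event_pt = event_pt,
    background_event_rate = background_event_rate,
    theta = theta,
    dup_rate = dup_rate,
    sex_marginal = norm_marginal(sex_marginal, "sex_marginal"),
    age_marginal = norm_marginal(age_marginal, "age_marginal"),
    occupation_marginal = norm_marginal(occupation_marginal,
                                        "occupation_marginal"),
    country_marginal = norm_marginal(country_marginal, "country_marginal"),
    outcome_mixture = norm_marginal(outcome_mixture, "outcome_mixture"),
    year_range = as.integer(year_range),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

sample_marg <- function(n, marginal) {
  out <- sample(names(marginal), n, replace = TRUE, prob = marginal)
  out[out == "NA"] <- NA_character_
  out
}

#' Generate a synthetic spontaneous-report dataset
#'
#' Draws `n_reports` primary reports per the configuration — independent
#' per-drug exposure (at least one drug per report enforced by redrawing),
#' logistic event assignment with the configured true odds ratios, i.i.d.
#' demographics — then appends `floor(dup_rate * n_reports)` exact duplicates
#' (fresh `report_id`, same case, date and drugs). Drug names come out
#' already standardized, with uppercase verbatim forms.
#'
#' Ground truth travels on attributes: `"truth"` (tibble of each drug's true
#' odds ratio) and `"duplicate_of"` (the `report_id` each injected duplicate
#' copies). Identical configurations generate bit-identical datasets; the
#' caller's RNG state is left untouched.
#'
#' @param config A [synthetic_config()].
#' @return A report tibble of `n_reports + floor(dup_rate * n_reports)` rows
#'   in the layout of [read_reports()].
#' @examples
#' reports <- generate_reports(synthetic_config(n_reports = 200, seed = 42))
#' nrow(reports)  # 220 (200 primaries + 20 duplicates)
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_reports_impl(config))
}

generate_reports_impl <- function(config) {
  n <- config$n_reports
  cat <- config$drug_catalog
  k <- nrow(cat)

  # per-drug exposure; redraw all-zero rows until every report has a drug
  expo <- matrix(stats::runif(n * k) < rep(cat$p, each = n), n, k)
  empty <- which(rowSums(expo) == 0L)
  while (length(empty)) {
    redraw <- matrix(stats::runif(length(empty) * k) < rep(cat$p, each = length(empty)),
                     length(empty), k)
    expo[empty, ] <- redraw
    empty <- empty[rowSums(redraw) == 0L]
  }

  # logistic event model: odds multiplied by theta per exposed drug
  base_odds <- config$background_event_rate / (1 - config$background_event_rate)
  log_odds <- log(base_odds) + as.vector(expo %*% log(config$theta))
  p_event <- stats::plogis(log_odds)
  event <- stats::runif(n) < p_event

  hit <- which(expo, arr.ind = TRUE)
  cols <- hit[order(hit[, 1]), 2]
  lens <- tabulate(hit[, 1], n)
  drug_std <- chop_by(cat$name[cols], lens)
  drug_verb <- chop_by(toupper(cat$name)[cols], lens)
  drug_comb <- chop_by(cat$is_combination[cols], lens)

  reactions <- as.list(sample(noise_pts, n, replace = TRUE))
  if (any(event)) {
    reactions[event] <- purrr::map(reactions[event],
                                   function(x) c(config$event_pt, x))
  }

  outcome_draw <- sample_marg(n, config$outcome_mixture)
  outcomes <- as.list(outcome_draw)
  none <- is.na(outcome_draw) | outcome_draw == "NONE"
  outcomes[none] <- list(character())

  age_band <- sample_marg(n, config$age_marginal)
  age <- rep(NA_real_, n)
  b1 <- which(age_band == "<18"); b2 <- which(age_band == "18-60")
  b3 <- which(age_band == ">=60")
  age[b1] <- sample(0:17, length(b1), replace = TRUE)
  age[b2] <- sample(18:59, length(b2), replace = TRUE)
  age[b3] <- sample(60:99, length(b3), replace = TRUE)

  year <- sample(config$year_range, n, replace = TRUE)
  date <- lubridate::make_date(year, sample(1:12, n, replace = TRUE),
                               sample(1:28, n, replace = TRUE))

  reports <- tibble(
    report_id = sprintf("R%07d", seq_len(n)),
    case_id = sprintf("C%07d", seq_len(n)),
    receipt_date = date,
    age_years = age,
    sex = sample_marg(n, config$sex_marginal),
    occupation = sample_marg(n, config$occupation_marginal),
    country = sample_marg(n, config$country_marginal),
    drug_verbatim = drug_verb,
    drug_standardized = drug_std,
    drug_combination = drug_comb,
    reactions = reactions,
    outcomes = outcomes
  )

  n_dup <- floor(config$dup_rate * n)
  if (n_dup > 0) {
    src <- sample(n, n_dup)
    dups <- reports[src, ]
    dups$report_id <- paste0(dups$report_id, "D")
    reports <- dplyr::bind_rows(reports, dups)
    attr(reports, "duplicate_of") <- setNames(reports$report_id[src],
                                              dups$report_id)
  } else {
    attr(reports, "duplicate_of") <- setNames(character(), character())
  }
  attr(reports, "truth") <- tibble(drug = names(config$theta),
                                   theta = unname(config$theta))
  reports
}
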