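#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for the printed percentages and
#' odds-ratio tables: 0.5 always rounds away from zero, unlike [round()]'s
#' round-half-to-even. A tiny epsilon guards against decimal values that are
#' not exactly representable in binary.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))          # 1 2 3
#' round_half_up(44.0355, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Case-fold and collapse internal whitespace; the normal form used for drug
# names and MedDRA preferred terms throughout. The regex pass only runs when
# some element actually needs it, which keeps bulk counting paths cheap.
normalize_label <- function(x) {
  x <- trimws(tolower(x))
  if (any(grepl("\\s\\s|[\t\n\r]", x))) x <- stringr::str_squish(x)
  x
}

# Chop a flat vector back into a list of per-report vectors; `flat` must be
# in report order.
chop_by <- function(flat, lens) {
  vctrs::vec_chop(flat, sizes = as.integer(lens))
}

# For each element of a list of character vectors, TRUE iff any member is in
# `values` (both sides already normalized). Vectorized over the whole list via
# a single unlist pass, so it stays fast at 1e5+ reports.
list_any_in <- function(lst, values) {
  lens <- lengths(lst)
  out <- logical(length(lst))
  if (sum(lens) == 0L) return(out)
  flat <- unlist(lst, use.names = FALSE)
  hit <- flat %in% values
  if (any(hit)) {
    grp <- rep.int(seq_along(lst), lens)
    out[unique(grp[hit])] <- TRUE
  }
  out
}

# Standardized-if-available drug names per report, normalized: unresolved
# entries fall back to the case-folded verbatim name.
drug_name_sets <- function(reports) {
  lens <- lengths(reports$drug_standardized)
  std <- unlist(reports$drug_standardized, use.names = FALSE)
  verb <- unlist(reports$drug_verbatim, use.names = FALSE)
  if (length(std)) {
    miss <- is.na(std)
    std[miss] <- verb[miss]
    std <- normalize_label(std)
  }
  chop_by(std, lens)
}

stopifnot_reports <- function(reports) {
  needed <- c(
    "report_id", "case_id", "receipt_date", "age_years", "sex", "occupation",
    "country", "drug_verbatim", "drug_standardized", "drug_combination",
    "reactions", "outcomes"
  )
  missing <- setdiff(needed, names(reports))
  if (length(missing)) {
    stop("not a report table; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(reports)
}
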