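#' @export
print.pv_screen <- function(x, ...) {
  ev <- attr(x, "event")
  cat("# Disproportionality screen", if (!is.null(ev)) paste0("(event: ", ev, ")"),
      "\n")
  cat("# ", attr(x, "n_reports") %||% NA, " reports, ",
      sum(x$signal, na.rm = TRUE), "/", nrow(x), " signals\n", sep = "")
  NextMethod()
}

#' Tidy a disproportionality screen
#'
#' @param x A `pv_screen` from [screen_drugs()] or [rollup_categories()].
#' @param ... Unused.
#' @return A plain tibble, one row per drug (or category), with the counts,
#'   ROR and 95% CI, PRR and chi-square, the per-criterion verdicts, and the
#'   combined `signal` call.
#' @method tidy pv_screen
#' @export
tidy.pv_screen <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pv_screen")
  attr(out, "event") <- NULL
  attr(out, "min_reports") <- NULL
  attr(out, "n_reports") <- NULL
  as_tibble(out)
}

#' One-row summary of a disproportionality screen
#'
#' @param x A `pv_screen`.
#' @param ... Unused.
#' @return Tibble with `event`, `n_reports` (dataset size), `n_groups`
#'   (drugs or categories screened), `n_signals`, `n_ror_signals`,
#'   `n_prr_signals`.
#' @method glance pv_screen
#' @export
glance.pv_screen <- function(x, ...) {
  tibble(
    event = attr(x, "event") %||% NA_character_,
    n_reports = attr(x, "n_reports") %||% NA_integer_,
    n_groups = nrow(x),
    n_signals = sum(x$signal, na.rm = TRUE),
    n_ror_signals = sum(x$ror_criterion_met, na.rm = TRUE),
    n_prr_signals = sum(x$prr_criterion_met, na.rm = TRUE)
  )
}

#' Forest-style plot of a disproportionality screen
#'
#' Plots each drug's (or category's) ROR with its 95% interval on a log
#' scale, signals highlighted, with a reference line at 1.
#'
#' @param object A `pv_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pv_screen
#' @export
autoplot.pv_screen <- function(object, ...) {
  df <- tidy(object)
  label_col <- if ("drug" %in% names(df)) "drug" else "category"
  df <- df[!is.na(df$ror), ]
  df$label <- stats::reorder(df[[label_col]], df$ror)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper), height = 0.25
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$signal), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey30")) +
    ggplot2::labs(
      x = "Reporting odds ratio (95% CI, log scale)", y = NULL,
      colour = "Signal",
      title = paste0("Disproportionality screen: ",
                     attr(object, "event") %||% "")
    ) +
    ggplot2::theme_minimal()
}

#' Line plot of yearly report counts
#'
#' @param reports Report tibble.
#' @return A ggplot object (undated reports are omitted from the line).
#' @export
plot_yearly_counts <- function(reports) {
  df <- counts_by_year(reports)
  df <- df[!is.na(df$year), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Receipt year", y = "Reports") +
    ggplot2::theme_minimal()
}

#' Bar plot of the most-severe-outcome distribution
#'
#' @param reports Report tibble.
#' @return A ggplot object.
#' @export
plot_outcomes <- function(reports) {
  df <- outcome_distribution(reports)
  df$outcome <- factor(df$outcome, levels = df$outcome)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Most severe outcome", y = "Reports") +
    ggplot2::theme_minimal()
}

#' Bar plot of the demographic composition
#'
#' @param reports Report tibble.
#' @return A ggplot object faceted by variable.
#' @export
plot_demographics <- function(reports) {
  df <- summarize_demographics(reports)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Reports") +
    ggplot2::theme_minimal()
}
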