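#' @import ggplot2
NULL

#' Plot the four completion quadrants
#'
#' @param quadrants Output of [quadrant_percentages()].
#' @return A ggplot.
#' @export
plot_quadrants <- function(quadrants) {
  ggplot(quadrants, aes(x = .data$status, y = .data$pct, fill = .data$status)) +
    geom_col(show.legend = FALSE) +
    geom_text(aes(label = sprintf("%.1f%%", .data$pct)), vjust = -0.3, size = 3) +
    labs(x = NULL, y = "% of applicable form instances") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 20, hjust = 1))
}

#' Plot the color-coded subject status grid
#'
#' Blue = completed without errors, green = completed with errors, yellow =
#' not collected by design; incomplete/unknown cells stay grey.
#'
#' @param cells Output of [cell_codes()].
#' @return A ggplot.
#' @export
plot_status_grid <- function(cells) {
  ggplot(cells, aes(x = interaction(.data$form_id, .data$visit, sep = "\n"),
                    y = .data$subject_id, fill = .data$color)) +
    geom_tile(color = "white") +
    scale_fill_manual(values = c(blue = "#4477AA", green = "#228833",
                                 yellow = "#CCBB44"),
                      na.value = "grey85", name = NULL) +
    labs(x = NULL, y = "subject") +
    theme_minimal() +
    theme(axis.text.x = element_text(size = 6),
          axis.text.y = element_text(size = 5))
}

#' Plot UpSet-style completeness combination counts
#'
#' Vertical bars per exclusive form combination, faceted by site.
#'
#' @param counts Output of [combination_counts()].
#' @return A ggplot.
#' @export
plot_combination_counts <- function(counts) {
  d <- counts |> mutate(combo = if_else(.data$combo == "", "(none)", .data$combo))
  ggplot(d, aes(x = stats::reorder(.data$combo, -.data$n), y = .data$n)) +
    geom_col(fill = "#4477AA") +
    facet_wrap(~site_id, scales = "free_x") +
    labs(x = "completed without errors", y = "subjects",
         title = sprintf("Completeness combinations (%s anchor)",
                         unique(d$anchor))) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1, size = 6))
}

#' Plot biomarker score distributions
#'
#' Violin + jitter per visit, colored by cohort, faceted by form.
#'
#' @param scores Output of [score_forms()].
#' @return A ggplot.
#' @export
plot_score_distributions <- function(scores) {
  ggplot(scores |> filter(!is.na(.data$score)),
         aes(x = .data$visit, y = .data$score, fill = .data$cohort)) +
    geom_violin(alpha = 0.6, position = position_dodge(width = 0.8)) +
    facet_wrap(~form_id, scales = "free_y") +
    labs(x = "visit", y = "score") +
    theme_minimal()
}

#' Plot PRO error types by site and delivery instrument
#'
#' @param breakdown Output of [instrument_breakdown()].
#' @return A ggplot.
#' @export
plot_instrument_breakdown <- function(breakdown) {
  ggplot(breakdown, aes(x = .data$site_id, y = .data$pct,
                        fill = .data$error_type)) +
    geom_col(position = "dodge") +
    facet_wrap(~form_id) +
    labs(x = "site (MCC1 sites deliver via REDCap, MCC2 via MyDataHelps)",
         y = "% of PRO errors", fill = "error type") +
    theme_minimal()
}

#' Plot monthly error counts per domain
#'
#' @param counts Output of [monthly_counts()].
#' @return A ggplot.
#' @export
plot_monthly_errors <- function(counts) {
  ggplot(counts, aes(x = .data$month, y = .data$count, color = .data$domain)) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = NULL, y = "errors per month", color = "domain") +
    theme_minimal()
}

#' Autoplot a trend fit
#'
#' Observed monthly counts with the fitted exponential trend overlaid.
#'
#' @param object A `trend_fit` from [fit_trend()] or [pooled_trend()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trend_fit <- function(object, ...) {
  d <- object$model$model
  d$fitted <- stats::fitted(object$model)
  p <- ggplot(d, aes(x = .data$idx))
  if ("domain" %in% names(d)) {
    p <- p + geom_point(aes(y = .data$count, color = .data$domain)) +
      geom_line(aes(y = .data$fitted, color = .data$domain))
  } else {
    p <- p + geom_point(aes(y = .data$count)) +
      geom_line(aes(y = .data$fitted), color = "#4477AA")
  }
  p + labs(x = "study month", y = "errors per month",
           title = sprintf("%s: %0.1f%% change over %d months (%s)",
                           object$domain, object$pct_change,
                           object$span_months, object$family)) +
    theme_minimal()
}
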