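#' Monthly error-count series per domain
#'
#' Buckets flags by calendar month of their `flag_date`, per CRF domain,
#' zero-filling months without flags between each domain's first and last
#' flagged month so that every series is contiguous over its observed span.
#' Summing the per-domain series month-wise gives the total series.
#'
#' @param flags Flag table from [run_checks()] (or [replay_fixture()]).
#' @return Tibble `domain`, `month` (first day of month), `count`.
#' @export
monthly_counts <- function(flags) {
  if (!nrow(flags)) {
    return(tibble(domain = character(), month = as.Date(character()),
                  count = integer()))
  }
  flags |>
    mutate(month = month_floor(.data$flag_date)) |>
    count(.data$domain, .data$month, name = "count") |>
    group_by(.data$domain) |>
    tidyr::complete(month = seq(min(.data$month), max(.data$month), by = "month"),
                    fill = list(count = 0L)) |>
    ungroup() |>
    arrange(.data$domain, .data$month)
}

#' Observed percent change over a series' span
#'
#' The raw difference between the first and last monthly counts of one
#' domain's series, as a percentage of the first:
#' `100 * (last - first) / first`, rounded to one decimal (half away from
#' zero). Undefined (returned as `NA` with a warning) when the first count
#' is zero.
#'
#' @param series Tibble `month`, `count` for a single domain, ordered by
#'   month (as returned by [monthly_counts()] filtered to one domain).
#' @return Length-one numeric percentage.
#' @export
observed_percent_change <- function(series) {
  if (nrow(series) < 2) stop_crfqa("series needs at least 2 observation months")
  first <- series$count[1]
  last <- series$count[nrow(series)]
  if (first == 0) {
    warning("first monthly count is zero; observed % change undefined",
            call. = FALSE)
    return(NA_real_)
  }
  round_half_up(100 * (last - first) / first, 1)
}

new_trend_fit <- function(model, family, domain, slope, span, dispersion, n) {
  pct_change <- 100 * (exp(slope * span) - 1)
  structure(
    list(model = model, family = family, domain = domain, slope = slope,
         span_months = span,
         monthly_pct_change = 100 * (exp(slope) - 1),
         pct_change = pct_change, dispersion = dispersion, nobs = n),
    class = "trend_fit"
  )
}

pearson_dispersion <- function(model) {
  df <- stats::df.residual(model)
  if (df <= 0) return(NA_real_)
  sum(stats::residuals(model, type = "pearson")^2) / df
}

fit_count_model <- function(formula, data, dispersion_cutoff = 2) {
  pois <- stats::glm(formula, data = data, family = stats::poisson())
  disp <- pearson_dispersion(pois)
  if (!is.na(disp) && disp > dispersion_cutoff) {
    nb <- tryCatch(
      suppressWarnings(MASS::glm.nb(formula, data = data)),
      error = function(e) NULL
    )
    if (!is.null(nb)) return(list(model = nb, family = "nbinom", dispersion = disp))
  }
  list(model = pois, family = "poisson", dispersion = disp)
}

#' Fit a monthly error-trend model for one domain
#'
#' Count regression of monthly error counts on a linear month index with a
#' log link: Poisson by default, switching to a negative-binomial fit when
#' the Pearson dispersion statistic exceeds `dispersion_cutoff`. The
#' model-estimated percent change over the domain's span of `D` months is
#' `100 * (exp(beta * D) - 1)` where `beta` is the fitted slope (log count
#' per month); a series lying on an exact exponential is recovered exactly.
#'
#' @param series Tibble `month`, `count` for one domain, with at least 3
#'   observation months and not all zero.
#' @param domain Label stored on the fit.
#' @param dispersion_cutoff Pearson-dispersion threshold for the
#'   negative-binomial switch (default 2).
#' @return A `trend_fit` object; see [tidy.trend_fit()] and
#'   [glance.trend_fit()].
#' @export
fit_trend <- function(series, domain = "domain", dispersion_cutoff = 2) {
  if (nrow(series) < 3) stop_crfqa("trend fit needs >= 3 observation months")
  if (all(series$count == 0)) {
    stop_crfqa("degenerate series: all monthly counts are zero")
  }
  d <- series |>
    mutate(idx = months_between(min(.data$month), .data$month))
  f <- fit_count_model(count ~ idx, d, dispersion_cutoff)
  new_trend_fit(f$model, f$family, domain,
                slope = stats::coef(f$model)[["idx"]],
                span = max(d$idx), dispersion = f$dispersion, n = nrow(d))
}

#' Pooled error-trend model across domains
#'
#' Single count-regression over all domains with domain-level intercepts
#' and a shared slope (`count ~ domain + month`), quantifying the overall
#' change in monthly error counts over the study span while accounting for
#' level differences between CRF domains. The percent change is evaluated
#' over the overall span (first to last observed month across domains).
#'
#' @param counts Tibble `domain`, `month`, `count` from [monthly_counts()],
#'   with at least 2 domains.
#' @inheritParams fit_trend
#' @return A `trend_fit` with `domain = "pooled"`.
#' @export
pooled_trend <- function(counts, dispersion_cutoff = 2) {
  if (dplyr::n_distinct(counts$domain) < 2) {
    stop_crfqa("pooled trend needs >= 2 domains")
  }
  d <- counts |>
    mutate(idx = months_between(min(.data$month), .data$month),
           domain = factor(.data$domain))
  f <- fit_count_model(count ~ domain + idx, d, dispersion_cutoff)
  new_trend_fit(f$model, f$family, "pooled",
                slope = stats::coef(f$model)[["idx"]],
                span = max(d$idx), dispersion = f$dispersion, n = nrow(d))
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> %s (%s): slope %+0.4f log-count/month (%0.1f%%/month),\n  %0.1f%% change over %d months; dispersion %s, n = %d\n",
    x$domain, x$family, x$slope, x$monthly_pct_change, x$pct_change,
    x$span_months,
    ifelse(is.na(x$dispersion), "NA", sprintf("%0.2f", x$dispersion)), x$nobs
  ))
  invisible(x)
}

#' Tidy a trend fit
#'
#' Broom-style one-row-per-term coefficient table.
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.trend_fit <- function(x, ...) {
  s <- stats::coef(summary(x$model))
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' Glance at a trend fit
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return One-row tibble: `domain`, `family`, `slope`,
#'   `monthly_pct_change`, `span_months`, `pct_change`, `dispersion`,
#'   `nobs`.
#' @export
glance.trend_fit <- function(x, ...) {
  tibble(domain = x$domain, family = x$family, slope = x$slope,
         monthly_pct_change = x$monthly_pct_change,
         span_months = x$span_months, pct_change = x$pct_change,
         dispersion = x$dispersion, nobs = x$nobs)
}

#' Trend summary table
#'
#' One row per domain with the first/last observation month and count, the
#' observed percent change (raw difference between first and last counts),
#' and the model-estimated percent change from [fit_trend()]; plus a
#' `Total` row whose first/last counts are the sums of the per-domain
#' first/last counts (domains may start and end in different months, so the
#' total is a sum of endpoints, not a single calendar month) and whose
#' model estimate comes from the shared-slope [pooled_trend()].
#'
#' @param flags Flag table.
#' @param fit Also fit per-domain and pooled models (default `TRUE`; the
#'   observed columns never depend on it).
#' @return Tibble `domain`, `first_month`, `first_count`, `last_month`,
#'   `last_count`, `observed_pct_change`, `model_pct_change`.
#' @export
trend_summary <- function(flags, fit = TRUE) {
  counts <- monthly_counts(flags)
  per_domain <- counts |>
    summarise(
      first_month = min(.data$month),
      first_count = .data$count[which.min(.data$month)],
      last_month = max(.data$month),
      last_count = .data$count[which.max(.data$month)],
      n_months = dplyr::n(),
      .by = "domain"
    ) |>
    mutate(observed_pct_change = purrr::map2_dbl(
      .data$first_count, .data$last_count,
      ~ if (.x == 0) NA_real_ else round_half_up(100 * (.y - .x) / .x, 1)
    ))
  if (fit) {
    per_domain$model_pct_change <- purrr::map_dbl(per_domain$domain, function(dm) {
      s <- counts |> filter(.data$domain == dm)
      if (nrow(s) < 3) return(NA_real_)
      round_half_up(fit_trend(s, dm)$pct_change, 1)
    })
  } else {
    per_domain$model_pct_change <- NA_real_
  }
  total <- tibble(
    domain = "Total",
    first_month = as.Date(NA), first_count = sum(per_domain$first_count),
    last_month = as.Date(NA), last_count = sum(per_domain$last_count),
    n_months = NA_integer_,
    observed_pct_change = if (sum(per_domain$first_count) == 0) NA_real_ else
      round_half_up(100 * (sum(per_domain$last_count) -
                             sum(per_domain$first_count)) /
                      sum(per_domain$first_count), 1),
    model_pct_change = if (fit && dplyr::n_distinct(counts$domain) >= 2) {
      round_half_up(pooled_trend(counts)$pct_change, 1)
    } else NA_real_
  )
  bind_rows(per_domain |> arrange(.data$domain), total) |>
    select(-"n_months")
}
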