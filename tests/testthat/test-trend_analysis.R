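flag_stub <- function(domain, dates) {
  tibble::tibble(
    subject_id = paste0("P", seq_along(dates)), site_id = "S11",
    cohort = "TKA", domain = domain, form_id = "x", visit = "baseline",
    check_id = "c", kind = "missingness", fields = "", values = "",
    flag_date = as.Date(dates), delivery_instrument = "in-person",
    message = "m"
  )
}

test_that("monthly bucketing zero-fills the span", {
  flags <- flag_stub("Imaging", c("2024-03-05", "2024-03-20", "2024-03-31",
                                  "2024-05-02"))
  mc <- monthly_counts(flags)
  expect_equal(mc$count, c(3L, 0L, 1L))
  expect_equal(mc$month, as.Date(c("2024-03-01", "2024-04-01", "2024-05-01")))
  expect_equal(nrow(monthly_counts(flags[0, ])), 0L)
})

test_that("domain series sum month-wise to the total series", {
  cfg <- small_config(seed = 41, injection_probability = 0.2)
  sim <- simulate_study(cfg)
  flags <- run_checks(study_records(sim), cfg$registry, cfg$schema)
  mc <- monthly_counts(flags)
  total_by_month <- dplyr::summarise(mc, count = sum(count), .by = month)
  direct <- dplyr::count(
    dplyr::mutate(flags, month = lubridate::floor_date(flag_date, "month")),
    month, name = "count")
  joined <- dplyr::left_join(total_by_month, direct, by = "month",
                             suffix = c("", ".direct"))
  expect_equal(joined$count,
               ifelse(is.na(joined$count.direct), 0L, joined$count.direct))
})

test_that("observed percent change matches first/last arithmetic", {
  mk <- function(first, last) tibble::tibble(
    month = as.Date(c("2024-03-01", "2024-04-01", "2025-08-01")),
    count = c(first, 3L, last)
  )
  expect_equal(observed_percent_change(mk(16, 1)), -93.8)
  expect_equal(observed_percent_change(mk(40, 6)), -85.0)
  expect_equal(observed_percent_change(mk(5, 5)), 0.0)
  expect_warning(out <- observed_percent_change(mk(0, 4)), "undefined")
  expect_true(is.na(out))
  expect_error(observed_percent_change(mk(1, 1)[1, ]), "at least 2")
})

test_that("exact exponential series are recovered exactly", {
  series <- tibble::tibble(
    month = seq(as.Date("2024-01-01"), by = "month", length.out = 4),
    count = c(8, 4, 2, 1)
  )
  fit <- fit_trend(series, "exact")
  expect_equal(fit$monthly_pct_change, -50, tolerance = 1e-6)
  expect_equal(fit$pct_change, -87.5, tolerance = 1e-6)
  expect_equal(fit$span_months, 3)
  expect_equal(fit$family, "poisson")

  flat <- series
  flat$count <- rep(5, 4)
  fit0 <- fit_trend(flat, "flat")
  expect_equal(fit0$slope, 0, tolerance = 1e-8)
  expect_equal(fit0$pct_change, 0, tolerance = 1e-6)

  flat$count <- rep(0, 4)
  expect_error(fit_trend(flat), "degenerate")
  expect_error(fit_trend(series[1:2, ]), ">= 3")
})

test_that("tidy and glance expose the fit in broom shape", {
  series <- tibble::tibble(
    month = seq(as.Date("2024-01-01"), by = "month", length.out = 6),
    count = c(30, 25, 18, 16, 12, 9)
  )
  fit <- fit_trend(series, "Imaging")
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "idx"))
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$domain, "Imaging")
  expect_equal(gl$slope, td$estimate[2], ignore_attr = TRUE)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("Monte-Carlo recovery of a 10% monthly decay is unbiased", {
  set.seed(4242)
  true_monthly <- -10 # percent
  beta <- log(1 + true_monthly / 100)
  est <- replicate(200, {
    lambda <- 40 * exp(beta * (0:11))
    series <- tibble::tibble(
      month = seq(as.Date("2024-01-01"), by = "month", length.out = 12),
      count = stats::rpois(12, lambda)
    )
    fit_trend(series)$monthly_pct_change
  })
  expect_lt(abs(mean(est) - true_monthly), 2)
})

test_that("pooled trend shares the slope across domains", {
  months <- seq(as.Date("2024-01-01"), by = "month", length.out = 6)
  one <- tibble::tibble(month = months, count = c(32, 16, 8, 4, 2, 1))
  counts <- dplyr::bind_rows(
    dplyr::mutate(one, domain = "Imaging"),
    dplyr::mutate(one, domain = "QST")
  )
  pooled <- pooled_trend(counts)
  per <- fit_trend(one, "Imaging")
  # identical series in every domain: pooled change equals per-domain change
  expect_equal(pooled$slope, per$slope, tolerance = 1e-6)
  expect_equal(pooled$pct_change, per$pct_change, tolerance = 1e-4)
  expect_error(pooled_trend(dplyr::mutate(one, domain = "Imaging")), ">= 2 domains")

  # pooled slope lies within the range of domain slopes on simulated data
  set.seed(99)
  sim_counts <- dplyr::bind_rows(purrr::map(c("A", "B", "C"), function(dm) {
    b <- log(1 - sample(c(0.05, 0.10, 0.15), 1))
    tibble::tibble(domain = dm, month = months,
                   count = stats::rpois(6, 30 * exp(b * (0:5))))
  }))
  slopes <- vapply(c("A", "B", "C"), function(dm) {
    fit_trend(sim_counts[sim_counts$domain == dm, ], dm)$slope
  }, numeric(1))
  ps <- pooled_trend(sim_counts)$slope
  expect_gte(ps, min(slopes) - 1e-9)
  expect_lte(ps, max(slopes) + 1e-9)
})

test_that("trend summary mirrors the per-domain endpoints and total", {
  flags <- dplyr::bind_rows(
    flag_stub("Imaging", c(rep("2024-03-10", 4), rep("2024-04-10", 2),
                           rep("2024-05-10", 1))),
    flag_stub("QST", c(rep("2024-03-15", 6), rep("2024-04-15", 3),
                       rep("2024-05-15", 2)))
  )
  ts <- trend_summary(flags)
  img <- ts[ts$domain == "Imaging", ]
  expect_equal(img$first_count, 4L)
  expect_equal(img$last_count, 1L)
  expect_equal(img$observed_pct_change, -75.0)
  tot <- ts[ts$domain == "Total", ]
  expect_equal(tot$first_count, 10L)
  expect_equal(tot$last_count, 3L)
  expect_equal(tot$observed_pct_change, -70.0)
  expect_false(is.na(tot$model_pct_change))
})
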