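test_that("form classification covers the five statuses exactly once each", {
  s <- example_study_schema()
  reg <- default_check_registry(s)
  w <- tiny_wide(s)
  w$gad7_complete <- c("2", "0", "")
  w$gad7_3 <- c("", "1", "1") # missing item on the complete instance -> error
  rec <- suppressMessages(as_tidy_records(w, s))
  flags <- run_checks(rec, reg, s)
  st <- classify_forms(rec, flags, s)

  pick <- function(subj, visit, form) {
    as.character(st$status[st$subject_id == subj & st$visit == visit &
                             st$form_id == form])
  }
  expect_equal(pick("A1", "baseline", "gad7"), "complete_with_error")
  expect_equal(pick("A1", "month3", "gad7"), "incomplete")
  expect_equal(pick("B2", "baseline", "gad7"), "unknown")
  # thoracic subject: functional testing excluded by design
  expect_equal(pick("B2", "baseline", "functional_testing"),
               "not_collected_by_design")
  # no status field record at all -> unknown
  expect_equal(pick("A1", "baseline", "imaging"), "unknown")
  # partition: exactly one status per (subject, visit, form)
  expect_equal(anyDuplicated(st[c("subject_id", "visit", "form_id")]), 0L)
})

test_that("invalid status codes are reported and classified unknown", {
  s <- example_study_schema()
  w <- tiny_wide(s)
  w$gad7_complete[1] <- "9"
  rec <- suppressWarnings(suppressMessages(as_tidy_records(w, s)))
  st <- classify_forms(rec, run_checks(rec, default_check_registry(s), s), s)
  expect_true("invalid_status_code" %in% schema_violations(st)$rule)
  expect_equal(
    as.character(st$status[st$subject_id == "A1" & st$visit == "baseline" &
                             st$form_id == "gad7"]),
    "unknown"
  )
})

test_that("quadrant percentages match hand enumeration and conserve 100", {
  st <- status_tbl(c(rep("complete_no_error", 5), rep("complete_with_error", 2),
                     rep("incomplete", 2), "unknown"))
  q <- quadrant_percentages(st)
  expect_equal(q$pct, c(50, 20, 20, 10))
  expect_equal(sum(q$n), 10)

  all_clean <- quadrant_percentages(status_tbl(rep("complete_no_error", 4)))
  expect_equal(all_clean$pct, c(100, 0, 0, 0))

  # design-excluded instances leave the denominator
  mixed <- status_tbl(c("complete_no_error", "not_collected_by_design"))
  expect_equal(sum(quadrant_percentages(mixed)$n), 1)

  empty <- quadrant_percentages(st, sites = "nowhere")
  expect_equal(sum(empty$n), 0)
  expect_true(all(is.na(empty$pct)))
})

test_that("quadrants sum to 100 on random simulated studies", {
  cfg <- small_config(seed = 21, injection_probability = 0.15)
  sim <- simulate_study(cfg)
  rec <- study_records(sim)
  st <- classify_forms(rec, run_checks(rec, cfg$registry, cfg$schema), cfg$schema)
  for (site in cfg$schema$sites$site_id) {
    q <- quadrant_percentages(st, sites = site)
    expect_equal(sum(100 * q$n / sum(q$n)), 100)
  }
})

test_that("streak statuses follow the due-visit completion rules", {
  s <- example_study_schema()
  bl <- tibble::tibble(subject_id = "P1", baseline_date = as.Date("2024-01-01"))
  as_of <- as.Date("2024-01-10") # only the baseline visit (day 0) is due

  st_clean <- status_tbl(rep("complete_no_error", 4), subject = rep("P1", 4),
                         form = c("imaging", "qst", "functional_testing",
                                  "blood_collection"))
  expect_equal(classify_streaks(st_clean, s, bl, as_of)$streak,
               "complete_streak_no_errors")

  st_err <- st_clean
  st_err$status[2] <- "complete_with_error"
  expect_equal(classify_streaks(st_err, s, bl, as_of)$streak,
               "streak_with_errors")

  st_inc <- st_clean
  st_inc$status[3] <- "incomplete"
  expect_equal(classify_streaks(st_inc, s, bl, as_of)$streak,
               "incomplete_streak")

  # a due visit with no status rows at all counts as incomplete
  as_of_late <- as.Date("2024-04-15") # postop + month3 now due
  expect_equal(classify_streaks(st_clean, s, bl, as_of_late)$streak,
               "incomplete_streak")
})

test_that("streak statuses partition subjects with a baseline date", {
  cfg <- small_config(seed = 22, injection_probability = 0.1)
  sim <- simulate_study(cfg)
  rec <- study_records(sim)
  st <- classify_forms(rec, run_checks(rec, cfg$registry, cfg$schema), cfg$schema)
  bl <- baseline_dates(rec)
  streaks <- classify_streaks(st, cfg$schema, bl, cfg$as_of)
  expect_equal(sort(streaks$subject_id), sort(bl$subject_id))
  expect_true(all(streaks$streak %in% c("complete_streak_no_errors",
                                        "streak_with_errors",
                                        "incomplete_streak")))
})

test_that("cell colors derive from status with tooltips on error cells", {
  st <- status_tbl(c("complete_no_error", "complete_with_error",
                     "not_collected_by_design", "incomplete"))
  flags <- tibble::tibble(subject_id = "P2", visit = "baseline",
                          form_id = "gad7", message = "missing GAD-7 item(s)")
  cells <- cell_codes(st, flags)
  expect_equal(cells$color, c("blue", "green", "yellow", NA))
  expect_equal(cells$tooltip[2], "missing GAD-7 item(s)")
  expect_true(is.na(cells$tooltip[1]))
})

test_that("combination counts match hand enumeration with marginals", {
  s <- example_study_schema()
  # 3 subjects, single due visit; completed subsets {gad7, phq9}, {gad7, phq9}, {gad7}
  bl <- tibble::tibble(subject_id = c("P1", "P2", "P3"),
                       baseline_date = as.Date("2024-06-01"))
  as_of <- as.Date("2024-06-10")
  st <- dplyr::bind_rows(
    status_tbl(c("complete_no_error", "complete_no_error"), subject = rep("P1", 2),
               form = c("gad7", "phq9")),
    status_tbl(c("complete_no_error", "complete_no_error"), subject = rep("P2", 2),
               form = c("gad7", "phq9")),
    status_tbl(c("complete_no_error", "incomplete"), subject = rep("P3", 2),
               form = c("gad7", "phq9"))
  )
  cc <- combination_counts(st, s, bl, as_of, "early",
                           tracked_forms = c("gad7", "phq9"))
  expect_equal(cc$n[cc$combo == "gad7+phq9"], 2)
  expect_equal(cc$n[cc$combo == "gad7"], 1)
  expect_equal(sum(cc$n), 3) # partition of the stratum

  marg <- combination_marginals(cc)
  expect_equal(marg$n[marg$form_id == "gad7"], 3)
  expect_equal(marg$n[marg$form_id == "phq9"], 2)
})

test_that("exclusive subsets agree with a brute-force oracle over 2^k subsets", {
  cfg <- small_config(seed = 23, injection_probability = 0.1)
  sim <- simulate_study(cfg)
  rec <- study_records(sim)
  st <- classify_forms(rec, run_checks(rec, cfg$registry, cfg$schema), cfg$schema)
  bl <- baseline_dates(rec)
  forms <- cfg$schema$forms$form_id # 6 tracked forms
  for (anchor in c("early", "late")) {
    cc <- suppressMessages(
      combination_counts(st, cfg$schema, bl, cfg$as_of, anchor,
                         tracked_forms = forms))
    in_stratum <- if (anchor == "early") {
      as.numeric(cfg$as_of - bl$baseline_date) < 35
    } else {
      cfg$as_of > lubridate::add_with_rollback(bl$baseline_date,
                                               lubridate::period(7, "months"))
    }
    membership <- crfqa:::completion_membership(
      st, cfg$schema, bl[in_stratum, ], cfg$as_of, forms)
    # brute force: enumerate all 2^6 subsets and count exact matches
    subj_sets <- split(membership$form_id[membership$complete],
                       membership$subject_id[membership$complete])
    all_subjects <- unique(membership$subject_id)
    oracle <- integer()
    for (mask in 0:(2^length(forms) - 1)) {
      subset <- forms[bitwAnd(mask, 2^(seq_along(forms) - 1)) > 0]
      n <- sum(vapply(all_subjects, function(p) {
        got_set <- subj_sets[[p]]
        if (is.null(got_set)) got_set <- character()
        setequal(got_set, subset)
      }, logical(1)))
      if (n > 0) oracle[paste(sort(subset), collapse = "|")] <- n
    }
    got <- stats::setNames(
      cc$n,
      vapply(cc$forms, function(f) paste(sort(f), collapse = "|"), character(1))
    )
    agg <- tapply(got, names(got), sum) # counts are per site; oracle is pooled
    expect_equal(sort(names(agg)), sort(names(oracle)))
    expect_equal(as.integer(agg[sort(names(agg))]),
                 as.integer(oracle[sort(names(agg))]))
    # conservation and marginal identity
    expect_equal(sum(cc$n), length(all_subjects))
    marg <- combination_marginals(cc)
    for (i in seq_len(nrow(marg))) {
      expect_equal(marg$n[i], sum(cc$n[cc$site_id == marg$site_id[i] &
                                         vapply(cc$forms, function(f)
                                           marg$form_id[i] %in% f, logical(1))]))
    }
  }
})

test_that("the UpSet membership matrix export matches the counts", {
  cfg <- small_config(seed = 24)
  sim <- simulate_study(cfg)
  rec <- study_records(sim)
  st <- classify_forms(rec, run_checks(rec, cfg$registry, cfg$schema), cfg$schema)
  bl <- baseline_dates(rec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_upset_matrix(st, cfg$schema, bl, cfg$as_of, "late", path)
  mat <- readr::read_csv(path, show_col_types = FALSE)
  cc <- combination_counts(st, cfg$schema, bl, cfg$as_of, "late")
  expect_equal(nrow(mat), sum(cc$n))
  marg <- combination_marginals(cc)
  for (i in seq_len(nrow(marg))) {
    expect_equal(sum(mat[[marg$form_id[i]]][mat$site_id == marg$site_id[i]]),
                 marg$n[i])
  }
})
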