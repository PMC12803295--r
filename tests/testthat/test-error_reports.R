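test_that("window bounds follow the decided 0-89 / 90-180 / 181+ convention", {
  as_of <- as.Date("2025-01-01")
  ages <- c(0, 89, 90, 180, 181, 400)
  got <- window_assign(as_of - ages, as_of)
  expect_equal(as.character(got),
               c("recent", "recent", "mid", "mid", "archive", "archive"))
  expect_error(window_assign(as_of + 1, as_of), "later than")
})

test_that("every flag lands in exactly one window and reports partition flags", {
  cfg <- small_config(seed = 31, injection_probability = 0.25)
  sim <- simulate_study(cfg)
  flags <- run_checks(study_records(sim), cfg$registry, cfg$schema)
  w <- window_assign(flags$flag_date, cfg$as_of)
  expect_false(any(is.na(w)))

  total <- 0L
  for (center in c("MCC1", "MCC2")) {
    for (cohort in cfg$schema$cohorts) {
      for (domain in unique(cfg$schema$forms$domain)) {
        per_window <- vapply(c("recent", "mid", "archive"), function(win) {
          nrow(build_report(flags, cfg$schema, center, cohort, domain, win,
                            cfg$as_of))
        }, integer(1))
        centers <- cfg$schema$sites$center[match(flags$site_id,
                                                 cfg$schema$sites$site_id)]
        stratum_n <- sum(centers == center & flags$cohort == cohort &
                           flags$domain == domain)
        expect_equal(sum(per_window), stratum_n)
        total <- total + sum(per_window)
      }
    }
  }
  expect_equal(total, nrow(flags))
})

test_that("reports filter to stratum x domain x window with fixed columns", {
  cfg <- small_config(seed = 32, injection_probability = 0.3)
  sim <- simulate_study(cfg)
  flags <- run_checks(study_records(sim), cfg$registry, cfg$schema)
  rep <- build_report(flags, cfg$schema, "MCC1", "TKA", "Imaging", "recent",
                      cfg$as_of)
  expect_s3_class(rep, "error_report")
  expect_equal(names(rep), c("subject_id", "site_id", "visit", "form",
                             "check_id", "fields", "values", "flag_date",
                             "message"))
  expect_true(all(rep$site_id %in% c("S11", "S12")))
  expect_true(all(rep$form == "imaging"))
  # empty stratum: valid empty report, not an error
  empty <- build_report(flags[0, ], cfg$schema, "MCC2", "thoracic", "QST",
                        "archive", cfg$as_of)
  expect_equal(nrow(empty), 0L)
})

test_that("exports carry identical content in csv, spreadsheet and html", {
  cfg <- small_config(seed = 33, injection_probability = 0.3)
  sim <- simulate_study(cfg)
  flags <- run_checks(study_records(sim), cfg$registry, cfg$schema)
  rep <- build_report(flags, cfg$schema, "MCC1", "TKA", "QST", "archive",
                      cfg$as_of)
  expect_gt(nrow(rep), 0)

  csv1 <- withr::local_tempfile(fileext = ".csv")
  csv2 <- withr::local_tempfile(fileext = ".csv")
  xlsx <- withr::local_tempfile(fileext = ".xml")
  html <- withr::local_tempfile(fileext = ".html")
  export_report(rep, csv1, "csv")
  export_report(rep, csv2, "csv")
  export_report(rep, xlsx, "xlsx")
  export_report(rep, html, "html")

  # byte-identical CSV across runs; round-trip preserves the row set
  expect_identical(readBin(csv1, "raw", file.size(csv1)),
                   readBin(csv2, "raw", file.size(csv2)))
  back <- readr::read_csv(csv1, col_types = readr::cols(.default = "c"))
  expect_equal(nrow(back), nrow(rep))
  expect_equal(back$subject_id, rep$subject_id)

  # spreadsheet XML carries the same cells
  doc <- xml2::read_xml(xlsx)
  cells <- xml2::xml_text(xml2::xml_find_all(doc, "//*[local-name()='Data']"))
  n_col <- ncol(rep)
  expect_equal(length(cells), (nrow(rep) + 1) * n_col)
  expect_equal(cells[seq_len(n_col)], names(rep))
  expect_equal(matrix(cells[-seq_len(n_col)], ncol = n_col, byrow = TRUE)[, 1],
               rep$subject_id)

  # html contains every subject id
  html_txt <- paste(readLines(html), collapse = "\n")
  expect_true(all(vapply(rep$subject_id, grepl, logical(1), x = html_txt,
                         fixed = TRUE)))

  expect_error(export_report(rep, csv1, "pdf"), "supported")
})

test_that("empty reports export with headers only", {
  cfg <- small_config(seed = 34, injection_probability = 0)
  sim <- simulate_study(cfg)
  flags <- run_checks(study_records(sim), cfg$registry, cfg$schema)
  rep <- build_report(flags, cfg$schema, "MCC1", "TKA", "Imaging", "recent",
                      cfg$as_of)
  path <- withr::local_tempfile(fileext = ".csv")
  export_report(rep, path, "csv")
  lines <- readLines(path)
  expect_equal(length(lines), 1L)
  expect_match(lines, "^subject_id,")
})

test_that("instrument breakdown tabulates PRO error types per site", {
  cfg <- small_config(seed = 35, pro_missingness = c(REDCap = 0.3, MyDataHelps = 0.3))
  sim <- simulate_study(cfg)
  flags <- run_checks(study_records(sim), cfg$registry, cfg$schema)
  bd <- instrument_breakdown(flags, cfg$schema)
  expect_true(all(bd$form_id %in% c("gad7", "phq9")))
  # percentages per (form, site) sum to 100
  sums <- dplyr::summarise(bd, s = sum(pct), .by = c(form_id, site_id))
  expect_true(all(abs(sums$s - 100) < 0.25))
  # MCC1 flags carry REDCap, MCC2 MyDataHelps
  expect_true(all(bd$delivery_instrument[startsWith(bd$site_id, "S1")] == "REDCap"))
  expect_true(all(bd$delivery_instrument[startsWith(bd$site_id, "S2")] == "MyDataHelps"))

  expect_equal(nrow(instrument_breakdown(flags[0, ], cfg$schema)), 0L)
})

test_that("matched injected missingness yields near-equal rates across instruments", {
  # one larger study, equal PRO missingness probability under both
  # instruments; rates must agree within binomial sampling error
  cfg <- simulation_config(seed = 36, enrollment_per_site_per_month = 6,
                           months_enrollment = 10,
                           injection_probability = 0,
                           pro_missingness = c(REDCap = 0.2, MyDataHelps = 0.2))
  sim <- simulate_study(cfg)
  rec <- study_records(sim)
  flags <- run_checks(rec, cfg$registry, cfg$schema)
  st <- classify_forms(rec, flags, cfg$schema)
  rates <- instrument_missingness_rate(flags, st, cfg$schema)
  expect_setequal(rates$delivery_instrument, c("REDCap", "MyDataHelps"))
  p_pool <- sum(rates$n_flagged) / sum(rates$n_instances)
  se <- sqrt(p_pool * (1 - p_pool) * sum(1 / rates$n_instances))
  expect_lt(abs(diff(rates$rate)), 3 * se + 1e-12)
})
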