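# Shared small study configurations used across test files. Sizes are kept
# small (tens of subjects) so each simulated study builds in well under a
# second.

small_config <- function(seed = 1, ...) {
  simulation_config(
    seed = seed,
    enrollment_per_site_per_month = 2,
    months_enrollment = 6,
    ...
  )
}

# One wide record row per subject x event built by hand, for ingest tests.
tiny_wide <- function(schema = example_study_schema()) {
  tibble::tibble(
    record_id = c("A1", "A1", "B2"),
    redcap_event_name = c("baseline", "month3", "baseline"),
    site_id = c("S11", "S11", "S21"),
    cohort = c("TKA", "TKA", "thoracic"),
    gad7_entrydate = c("2024-04-01", "2024-07-01", "2024-05-10"),
    gad7_1 = c("1", "2", "0"),
    gad7_2 = c("3", "0", "1"),
    gad7_3 = c("1", "1", "1"),
    gad7_4 = c("0", "2", "1"),
    gad7_5 = c("2", "0", "0"),
    gad7_6 = c("1", "1", "2"),
    gad7_7 = c("0", "0", "1"),
    gad7_complete = c("2", "2", "2")
  )
}

# Minimal status tibble in the shape classify_forms() returns.
status_tbl <- function(status, subject = paste0("P", seq_along(status)),
                       site = "S11", visit = "baseline", form = "gad7",
                       cohort = "TKA") {
  tibble::tibble(
    subject_id = subject, site_id = site, cohort = cohort, visit = visit,
    form_id = form,
    status = factor(status, levels = crfqa:::STATUS_LEVELS),
    n_flags = ifelse(status == "complete_with_error", 1L, 0L)
  )
}
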