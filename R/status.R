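STATUS_LEVELS <- c("complete_no_error", "complete_with_error", "incomplete",
                   "unknown", "not_collected_by_design")

#' Classify completion/error status of every form instance
#'
#' Assigns exactly one status to every (subject, visit, form) cell for the
#' visits a subject has event rows for:
#'
#' * `not_collected_by_design` — the form's applicability predicate
#'   excludes this cohort/visit;
#' * `unknown` — the form-completion status field is missing;
#' * `incomplete` — status coded 0 (incomplete) or 1 (unverified; treated
#'   as incomplete downstream);
#' * `complete_with_error` — status 2 with at least one raised flag;
#' * `complete_no_error` — status 2 and flag-free.
#'
#' Status values outside \{0, 1, 2, missing\} are recorded as schema
#' violations (see [schema_violations()]) and classified `unknown`.
#'
#' @param records Tidy records ([as_tidy_records()]).
#' @param flags Flag table from [run_checks()].
#' @param schema A [study_schema()].
#' @return Tibble `subject_id`, `site_id`, `cohort`, `visit`, `form_id`,
#'   `status`, `n_flags`.
#' @export
classify_forms <- function(records, flags, schema) {
  events <- records |> distinct(.data$subject_id, .data$site_id, .data$cohort,
                                .data$visit)
  grid <- events |>
    tidyr::expand_grid(form_id = schema$forms$form_id) |>
    left_join(applicability_grid(schema) |> mutate(applicable = TRUE),
              by = c("cohort", "visit", "form_id")) |>
    mutate(applicable = !is.na(.data$applicable))

  status_values <- records |>
    inner_join(schema$forms |> select("form_id", field_name = "status_field"),
               by = c("form_id", "field_name")) |>
    select("subject_id", "visit", "form_id", status_value = "value")

  flag_counts <- flags |>
    count(.data$subject_id, .data$visit, .data$form_id, name = "n_flags")

  out <- grid |>
    left_join(status_values, by = c("subject_id", "visit", "form_id")) |>
    left_join(flag_counts, by = c("subject_id", "visit", "form_id")) |>
    mutate(n_flags = tidyr::replace_na(.data$n_flags, 0L))

  bad <- out |>
    filter(.data$applicable, !is.na(.data$status_value),
           !.data$status_value %in% c("0", "1", "2"))
  out <- out |>
    mutate(status = dplyr::case_when(
      !.data$applicable ~ "not_collected_by_design",
      is.na(.data$status_value) ~ "unknown",
      !.data$status_value %in% c("0", "1", "2") ~ "unknown",
      .data$status_value %in% c("0", "1") ~ "incomplete",
      .data$n_flags > 0 ~ "complete_with_error",
      .default = "complete_no_error"
    ) |> factor(levels = STATUS_LEVELS)) |>
    select("subject_id", "site_id", "cohort", "visit", "form_id", "status",
           "n_flags") |>
    arrange(.data$site_id, .data$subject_id,
            match(.data$visit, schema$visits$visit),
            match(.data$form_id, schema$forms$form_id))

  viol <- if (nrow(bad)) {
    new_violation(
      sprintf("subject %s, visit %s, form %s", bad$subject_id, bad$visit,
              bad$form_id),
      "invalid_status_code",
      sprintf("status value '%s' outside {0,1,2,missing}", bad$status_value)
    )
  } else new_violation(character(), character(), character())
  attr(out, "violations") <- viol
  out
}

#' Four-quadrant completion percentages
#'
#' Percentages of form instances completed without errors, completed with
#' errors, incomplete, and of unknown completion status, over any selection
#' of sites, visits and forms. Instances that are not collected by design
#' are removed from the denominator; the four percentages sum to 100 before
#' rounding. Percentages are rounded to one decimal, half away from zero.
#'
#' @param statuses Output of [classify_forms()].
#' @param sites,visits,forms Optional filters (default: everything).
#' @return Tibble with one row per quadrant: `status`, `n`, `pct`. An empty
#'   selection yields the four rows with `n = 0` and `pct = NA`.
#' @export
quadrant_percentages <- function(statuses, sites = NULL, visits = NULL,
                                 forms = NULL) {
  sel <- statuses
  if (!is.null(sites)) sel <- sel |> filter(.data$site_id %in% sites)
  if (!is.null(visits)) sel <- sel |> filter(.data$visit %in% visits)
  if (!is.null(forms)) sel <- sel |> filter(.data$form_id %in% forms)
  sel <- sel |> filter(.data$status != "not_collected_by_design")
  quadrants <- setdiff(STATUS_LEVELS, "not_collected_by_design")
  counts <- sel |>
    count(status = factor(.data$status, levels = quadrants), .drop = FALSE,
          name = "n")
  total <- sum(counts$n)
  counts |>
    mutate(pct = if (total == 0) NA_real_ else
      round_half_up(100 * .data$n / total, 1))
}

#' Subject-level completion streaks over the primary biomarker forms
#'
#' A subject's streak summarizes the primary biomarker forms (default:
#' imaging, QST, functional testing, blood collection) across all visits
#' that are due as of a given date (nominal visit offset no greater than
#' the days elapsed since the subject's baseline). Forms not collected by
#' design are ignored. The three statuses partition evaluated subjects:
#'
#' * `complete_streak_no_errors` — every due primary form complete and
#'   flag-free;
#' * `streak_with_errors` — every due primary form complete, at least one
#'   with errors;
#' * `incomplete_streak` — any due primary form incomplete or unknown.
#'
#' @param statuses Output of [classify_forms()].
#' @param schema A [study_schema()].
#' @param baseline Tibble `subject_id`, `baseline_date` (see
#'   [baseline_dates()]). Subjects without a baseline date are excluded.
#' @param as_of Reference date.
#' @param primary_forms Character vector of form ids making up the primary
#'   biomarker set.
#' @return Tibble `subject_id`, `site_id`, `streak`.
#' @export
classify_streaks <- function(statuses, schema, baseline, as_of,
                             primary_forms = c("imaging", "qst",
                                               "functional_testing",
                                               "blood_collection")) {
  as_of <- as.Date(as_of)
  subjects <- statuses |>
    distinct(.data$subject_id, .data$site_id, .data$cohort) |>
    inner_join(baseline, by = "subject_id") |>
    filter(!is.na(.data$baseline_date))

  due <- subjects |>
    mutate(elapsed = as.numeric(as_of - .data$baseline_date)) |>
    tidyr::expand_grid(schema$visits) |>
    filter(.data$day_offset <= .data$elapsed) |>
    select("subject_id", "site_id", "cohort", "visit")

  grid <- due |>
    inner_join(applicability_grid(schema), by = c("cohort", "visit"),
               relationship = "many-to-many") |>
    filter(.data$form_id %in% primary_forms) |>
    left_join(statuses |> select("subject_id", "visit", "form_id", "status"),
              by = c("subject_id", "visit", "form_id")) |>
    mutate(status = as.character(.data$status) |> tidyr::replace_na("unknown"))

  grid |>
    summarise(
      streak = dplyr::case_when(
        any(.data$status %in% c("incomplete", "unknown")) ~ "incomplete_streak",
        any(.data$status == "complete_with_error") ~ "streak_with_errors",
        .default = "complete_streak_no_errors"
      ),
      .by = c("subject_id", "site_id")
    ) |>
    arrange(.data$site_id, .data$subject_id)
}

#' Color-coded status grid cells
#'
#' Derives the cell coloring of the interactive error-status table from
#' form statuses alone: blue for error-free completed data, green for
#' completed data with errors (tooltip carries the check messages), yellow
#' for data not collected by design. Incomplete/unknown cells have no
#' color (`NA`).
#'
#' @param statuses Output of [classify_forms()].
#' @param flags Flag table from [run_checks()] (source of tooltips).
#' @return Tibble `subject_id`, `visit`, `form_id`, `color`, `tooltip`.
#' @export
cell_codes <- function(statuses, flags) {
  tooltips <- flags |>
    summarise(tooltip = paste(.data$message, collapse = "; "),
              .by = c("subject_id", "visit", "form_id"))
  statuses |>
    mutate(color = dplyr::case_when(
      .data$status == "complete_no_error" ~ "blue",
      .data$status == "complete_with_error" ~ "green",
      .data$status == "not_collected_by_design" ~ "yellow",
      .default = NA_character_
    )) |>
    left_join(tooltips, by = c("subject_id", "visit", "form_id")) |>
    mutate(tooltip = if_else(.data$color == "green", .data$tooltip,
                             NA_character_)) |>
    select("subject_id", "site_id", "visit", "form_id", "color", "tooltip")
}

#' Baseline dates from tidy records
#'
#' The subject's baseline date is the earliest entry timestamp among their
#' baseline-visit records.
#'
#' @param records Tidy records.
#' @param baseline_visit Name of the baseline visit.
#' @return Tibble `subject_id`, `baseline_date`.
#' @export
baseline_dates <- function(records, baseline_visit = "baseline") {
  records |>
    filter(.data$visit == baseline_visit, !is.na(.data$entry_timestamp)) |>
    summarise(baseline_date = min(.data$entry_timestamp), .by = "subject_id")
}

# Which tracked forms a subject has "completed without errors": every
# applicable due instance of the form is complete_no_error, and at least
# one such instance exists.
completion_membership <- function(statuses, schema, baseline, as_of,
                                  tracked_forms) {
  as_of <- as.Date(as_of)
  subjects <- statuses |>
    distinct(.data$subject_id, .data$site_id, .data$cohort) |>
    inner_join(baseline, by = "subject_id")
  due <- subjects |>
    mutate(elapsed = as.numeric(as_of - .data$baseline_date)) |>
    tidyr::expand_grid(schema$visits) |>
    filter(.data$day_offset <= .data$elapsed) |>
    select("subject_id", "site_id", "cohort", "visit")
  due |>
    inner_join(applicability_grid(schema), by = c("cohort", "visit"),
               relationship = "many-to-many") |>
    filter(.data$form_id %in% tracked_forms) |>
    left_join(statuses |> select("subject_id", "visit", "form_id", "status"),
              by = c("subject_id", "visit", "form_id")) |>
    summarise(complete = all(.data$status == "complete_no_error") & n() > 0,
              .by = c("subject_id", "site_id", "form_id"))
}

#' UpSet-style completeness combination counts
#'
#' Counts subjects by the *exact* subset of tracked forms they have
#' completed without errors, per site, within a time-from-baseline stratum:
#' the `early` anchor keeps subjects less than 35 days past their baseline
#' visit (pre-surgery surveys and immediate post-op data expected
#' complete), the `late` anchor keeps subjects more than 7 calendar months
#' past baseline (end of the primary-endpoint survey window). Month
#' arithmetic clamps to month end. Subjects without a baseline date are
#' excluded with a message.
#'
#' @param statuses Output of [classify_forms()].
#' @param schema A [study_schema()].
#' @param baseline Tibble `subject_id`, `baseline_date`.
#' @param as_of Reference date.
#' @param anchor `"early"` (< 35 days post-baseline) or `"late"`
#'   (> 7 months post-baseline).
#' @param tracked_forms Forms making up the UpSet axes (default: all
#'   schema forms).
#' @return Tibble `anchor`, `site_id`, `combo` (form ids joined by `+`, in
#'   schema order; empty string for the empty set), `forms` (list-column),
#'   `n`. Exclusive subsets are disjoint; their counts sum to the stratum
#'   size. Per-form marginal totals come from [combination_marginals()].
#' @export
combination_counts <- function(statuses, schema, baseline, as_of,
                               anchor = c("early", "late"),
                               tracked_forms = schema$forms$form_id) {
  anchor <- match.arg(anchor)
  as_of <- as.Date(as_of)
  subjects <- statuses |> distinct(.data$subject_id)
  missing_baseline <- setdiff(subjects$subject_id, baseline$subject_id)
  if (length(missing_baseline)) {
    message(sprintf("excluding %d subject(s) without a baseline date",
                    length(missing_baseline)))
  }
  stratum <- baseline |>
    filter(!is.na(.data$baseline_date)) |>
    mutate(keep = if (anchor == "early") {
      as.numeric(as_of - .data$baseline_date) < 35
    } else {
      as_of > (.data$baseline_date %m+% lubridate::period(7, "months"))
    }) |>
    filter(.data$keep)

  membership <- completion_membership(statuses, schema,
                                      stratum |> select("subject_id", "baseline_date"),
                                      as_of, tracked_forms)
  if (!nrow(membership)) {
    return(tibble(anchor = character(), site_id = character(),
                  combo = character(), forms = list(), n = integer()))
  }
  form_order <- intersect(schema$forms$form_id, tracked_forms)
  membership |>
    filter(.data$complete) |>
    summarise(combo = paste(form_order[form_order %in% .data$form_id],
                            collapse = "+"),
              .by = c("subject_id", "site_id")) |>
    # subjects whose completed subset is empty still belong to the stratum
    right_join(membership |> distinct(.data$subject_id, .data$site_id),
               by = c("subject_id", "site_id")) |>
    mutate(combo = tidyr::replace_na(.data$combo, "")) |>
    count(.data$site_id, .data$combo, name = "n") |>
    mutate(anchor = anchor,
           forms = purrr::map(.data$combo, ~ if (nzchar(.x))
             strsplit(.x, "+", fixed = TRUE)[[1]] else character())) |>
    select("anchor", "site_id", "combo", "forms", "n") |>
    arrange(.data$site_id, dplyr::desc(.data$n), .data$combo)
}

#' @rdname combination_counts
#' @param counts Output of [combination_counts()].
#' @return `combination_marginals()`: tibble `anchor`, `site_id`,
#'   `form_id`, `n` — the total number of subjects whose completed subset
#'   contains each form (the UpSet horizontal bars).
#' @export
combination_marginals <- function(counts) {
  counts |>
    tidyr::unnest_longer("forms", values_to = "form_id") |>
    filter(!is.na(.data$form_id)) |>
    summarise(n = sum(.data$n), .by = c("anchor", "site_id", "form_id")) |>
    arrange(.data$site_id, dplyr::desc(.data$n))
}

#' Export a subject-by-form completion matrix for UpSet tools
#'
#' Writes the 0/1 membership matrix (one row per subject in the stratum,
#' one column per tracked form) consumed by standard UpSet plotting tools.
#'
#' @inheritParams combination_counts
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_upset_matrix <- function(statuses, schema, baseline, as_of, anchor,
                               path, tracked_forms = schema$forms$form_id) {
  counts <- combination_counts(statuses, schema, baseline, as_of, anchor,
                               tracked_forms)
  wide <- counts |>
    tidyr::uncount(.data$n, .id = "rep") |>
    mutate(row = dplyr::row_number()) |>
    tidyr::unnest_longer("forms", values_to = "form_id", keep_empty = TRUE)
  form_order <- intersect(schema$forms$form_id, tracked_forms)
  mat <- wide |>
    mutate(member = 1L) |>
    tidyr::pivot_wider(id_cols = c("row", "site_id"), names_from = "form_id",
                       values_from = "member", values_fill = 0L)
  mat$`NA` <- NULL
  for (f in setdiff(form_order, names(mat))) mat[[f]] <- 0L
  write_csv(mat |> select("site_id", all_of(form_order)), path)
  invisible(path)
}
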