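#' Define an edit check
#'
#' An edit check is a declarative rule evaluated per form instance (one
#' subject x visit x form). Seven kinds are supported:
#'
#' * `missingness`: any listed required field blank on a completed form;
#' * `pair_mismatch`: two duplicate-entry fields disagree beyond a
#'   tolerance (numeric) or at all (categorical);
#' * `conditional_missingness`: a trigger field equals a given value but a
#'   dependent field is blank;
#' * `chronology`: an ordered list of date/time fields is out of order;
#' * `location_mismatch`: performed-at and entered-for site designators
#'   (remote/index) disagree;
#' * `reason_unspecified`: a test is marked not completed but no reason is
#'   given;
#' * `range`: a numeric value falls outside its allowed range.
#'
#' @param check_id Unique identifier.
#' @param form_id Form the check applies to.
#' @param kind One of the seven kinds above.
#' @param ... Kind-specific parameters: `fields` (missingness, chronology),
#'   `field_a`/`field_b`/`tolerance` (pair_mismatch), `trigger_field`/
#'   `trigger_value`/`dependent_fields` (conditional_missingness),
#'   `performed_field`/`entered_field` (location_mismatch),
#'   `completed_field`/`reason_field` (reason_unspecified),
#'   `field`/`min`/`max` (range).
#' @param message Human-readable message attached to every flag the check
#'   raises.
#' @return One-row tibble with a `params` list-column; rows bind into a
#'   check registry.
#' @seealso [default_check_registry()], [run_checks()]
#' @export
check_definition <- function(check_id, form_id, kind, ..., message = check_id) {
  kinds <- c("missingness", "pair_mismatch", "conditional_missingness",
             "chronology", "location_mismatch", "reason_unspecified", "range")
  if (!kind %in% kinds) {
    stop_crfqa("unknown check kind '%s' (supported: %s)", kind,
               paste(kinds, collapse = ", "))
  }
  params <- list(...)
  if (kind == "chronology" && length(params$fields %||% character()) < 2) {
    stop_crfqa("chronology check '%s' must list >= 2 time/date fields", check_id)
  }
  if (kind == "pair_mismatch" && (params$tolerance %||% 0) < 0) {
    stop_crfqa("pair_mismatch check '%s': tolerance must be >= 0", check_id)
  }
  tibble(check_id = check_id, form_id = form_id, kind = kind,
         params = list(params), message = message)
}

check_fields <- function(def_row) {
  p <- def_row$params[[1]]
  unique(unlist(p[c("fields", "field_a", "field_b", "trigger_field",
                    "dependent_fields", "performed_field", "entered_field",
                    "completed_field", "reason_field", "field")],
                use.names = FALSE))
}

validate_registry <- function(registry, schema) {
  if (anyDuplicated(registry$check_id)) stop_crfqa("duplicate check_id in registry")
  for (i in seq_len(nrow(registry))) {
    row <- registry[i, ]
    if (!row$form_id %in% schema$forms$form_id) {
      stop_crfqa("check '%s' references unknown form '%s'", row$check_id, row$form_id)
    }
    own <- schema$fields$field_name[schema$fields$form_id == row$form_id]
    bad <- setdiff(check_fields(row), own)
    if (length(bad)) {
      stop_crfqa("check '%s' references field(s) not on form '%s': %s",
                 row$check_id, row$form_id, paste(bad, collapse = ", "))
    }
  }
  invisible(registry)
}

# --- per-kind evaluators -----------------------------------------------
# Each takes a wide instance table (one row per subject x visit, columns =
# the form's fields, character values with NA as missing) and returns a
# tibble(.row, fields, values) with one row per flagged instance.

#' Evaluate a single check kind over form instances
#'
#' These are the building blocks [run_checks()] assembles; they are
#' exported so that individual rules can be exercised directly. Each takes
#' a wide table of form instances (one row per subject x visit, one column
#' per field, character values, `NA` = missing) and returns a tibble with
#' `.row` (instance row index), `fields` (comma-separated implicated
#' fields) and `values` (the observed values) for each flagged instance.
#'
#' @param data Wide instance table.
#' @param fields Character vector of field names (for `check_missing`:
#'   required fields to test; for `check_chronology`: date/time fields in
#'   their required non-decreasing order).
#' @name check-kinds
NULL

col_or_na <- function(data, f) {
  if (f %in% names(data)) as.character(data[[f]]) else rep(NA_character_, nrow(data))
}

#' @rdname check-kinds
#' @export
check_missing <- function(data, fields) {
  miss <- purrr::map(fields, ~ is.na(col_or_na(data, .x)))
  hit <- Reduce(`|`, miss)
  idx <- which(hit)
  tibble(
    .row = idx,
    fields = purrr::map_chr(idx, function(i) {
      paste(fields[purrr::map_lgl(miss, ~ .x[i])], collapse = ",")
    }),
    values = ""
  )
}

#' @rdname check-kinds
#' @param field_a,field_b The duplicate-entry field pair.
#' @param tolerance Non-negative numeric tolerance; values differing by
#'   more than this are mismatched. Ignored for categorical comparison.
#' @param numeric Compare as numbers (default) or as categories.
#' @export
check_pair_mismatch <- function(data, field_a, field_b, tolerance = 0, numeric = TRUE) {
  a <- col_or_na(data, field_a)
  b <- col_or_na(data, field_b)
  if (numeric) {
    an <- as_num(a); bn <- as_num(b)
    hit <- !is.na(an) & !is.na(bn) & abs(an - bn) > tolerance
  } else {
    hit <- !is.na(a) & !is.na(b) & a != b
  }
  idx <- which(hit)
  tibble(.row = idx, fields = paste(field_a, field_b, sep = ","),
         values = paste(a[idx], b[idx], sep = ","))
}

#' @rdname check-kinds
#' @param trigger_field,trigger_value The condition under which the
#'   dependent fields are required.
#' @param dependent_fields Fields that must be present when the trigger
#'   holds.
#' @export
check_conditional_missing <- function(data, trigger_field, trigger_value,
                                      dependent_fields) {
  trig <- col_or_na(data, trigger_field)
  miss <- purrr::map(dependent_fields, ~ is.na(col_or_na(data, .x)))
  hit <- !is.na(trig) & trig == trigger_value & Reduce(`|`, miss)
  idx <- which(hit)
  tibble(
    .row = idx,
    fields = purrr::map_chr(idx, function(i) {
      paste(c(trigger_field,
              dependent_fields[purrr::map_lgl(miss, ~ .x[i])]), collapse = ",")
    }),
    values = trig[idx]
  )
}

#' @rdname check-kinds
#' @export
check_chronology <- function(data, fields) {
  # Times as minutes-of-day, dates as day numbers: either way a numeric
  # sequence that must be non-decreasing in the declared field order.
  vals <- purrr::map(fields, function(f) {
    x <- col_or_na(data, f)
    v <- parse_hm(x)
    d <- suppressWarnings(as.numeric(as.Date(x, format = "%Y-%m-%d")))
    if_else(is.na(v), d, v)
  })
  n <- nrow(data)
  out <- purrr::map_dfr(seq_len(n), function(i) {
    v <- purrr::map_dbl(vals, i)
    present <- which(!is.na(v))
    if (length(present) < 2) return(NULL)
    bad_pairs <- list()
    for (k in seq_len(length(present) - 1)) {
      for (l in (k + 1):length(present)) {
        if (v[present[k]] > v[present[l]]) {
          bad_pairs <- c(bad_pairs, list(c(present[k], present[l])))
        }
      }
    }
    if (!length(bad_pairs)) return(NULL)
    impl <- sort(unique(unlist(bad_pairs)))
    tibble(.row = i, fields = paste(fields[impl], collapse = ","),
           values = paste(purrr::map_chr(impl, ~ col_or_na(data, fields[.x])[i]),
                          collapse = ","))
  })
  if (!nrow(out)) tibble(.row = integer(), fields = character(), values = character())
  else out
}

#' @rdname check-kinds
#' @param performed_field,entered_field Site-designator fields
#'   (remote/index) that must agree.
#' @export
check_location_mismatch <- function(data, performed_field, entered_field) {
  check_pair_mismatch(data, performed_field, entered_field, numeric = FALSE)
}

#' @rdname check-kinds
#' @param completed_field Yes/no field stating whether the test was done.
#' @param reason_field Free-text reason required when not completed.
#' @export
check_reason_unspecified <- function(data, completed_field, reason_field) {
  comp <- col_or_na(data, completed_field)
  reason <- col_or_na(data, reason_field)
  hit <- !is.na(comp) & comp == "no" & is.na(reason)
  idx <- which(hit)
  tibble(.row = idx, fields = paste(completed_field, reason_field, sep = ","),
         values = comp[idx])
}

#' @rdname check-kinds
#' @param field Numeric field to range-check.
#' @param min,max Allowed inclusive bounds.
#' @export
check_range <- function(data, field, min, max) {
  v <- as_num(col_or_na(data, field))
  hit <- !is.na(v) & (v < min | v > max)
  idx <- which(hit)
  tibble(.row = idx, fields = field, values = col_or_na(data, field)[idx])
}

eval_check <- function(wide, def_row) {
  p <- def_row$params[[1]]
  switch(def_row$kind,
    missingness = check_missing(wide, p$fields),
    pair_mismatch = check_pair_mismatch(wide, p$field_a, p$field_b,
                                        p$tolerance %||% 0,
                                        p$numeric %||% TRUE),
    conditional_missingness = check_conditional_missing(
      wide, p$trigger_field, p$trigger_value, p$dependent_fields),
    chronology = check_chronology(wide, p$fields),
    location_mismatch = check_location_mismatch(wide, p$performed_field,
                                                p$entered_field),
    reason_unspecified = check_reason_unspecified(wide, p$completed_field,
                                                  p$reason_field),
    range = check_range(wide, p$field, p$min, p$max)
  )
}

# Wide per-instance view of one form's records: one row per subject x
# visit, with metadata and a status/completeness column.
form_instances <- function(records, schema, form) {
  status_field <- schema$forms$status_field[schema$forms$form_id == form]
  wide <- records |>
    filter(.data$form_id == form) |>
    select("subject_id", "site_id", "cohort", "visit", "entry_timestamp",
           "delivery_instrument", "field_name", "value") |>
    tidyr::pivot_wider(names_from = "field_name", values_from = "value")
  wide$.status <- col_or_na(wide, status_field)
  wide
}

#' Run a check registry over tidy records
#'
#' Evaluates every check in the registry against the tidy observation
#' records and returns a deterministic, stably ordered flag table. Checks
#' are evaluated only on form instances whose status field says complete
#' (code 2): blanks on incomplete forms count towards "incomplete", not
#' towards "error", which keeps the completion quadrants disjoint. Each
#' flag carries the domain, the implicated fields and observed values, and
#' a `flag_date` equal to the entry timestamp of the flagged form instance
#' (the latest entry date among implicated records), which downstream
#' report windows and monthly trend series key on.
#'
#' @param records Tidy records from [load_records()]/[as_tidy_records()].
#' @param registry Check registry (rows from [check_definition()]).
#' @param schema A [study_schema()].
#' @return Flag tibble, one row per (subject, visit, check) at most, sorted
#'   by site, subject, visit order, check: columns `subject_id`, `site_id`,
#'   `cohort`, `domain`, `form_id`, `visit`, `check_id`, `kind`, `fields`,
#'   `values`, `flag_date`, `delivery_instrument`, `message`.
#' @export
run_checks <- function(records, registry, schema) {
  validate_registry(registry, schema)
  flags <- purrr::map_dfr(unique(registry$form_id), function(form) {
    wide <- form_instances(records, schema, form)
    wide <- wide[!is.na(wide$.status) & wide$.status == "2", , drop = FALSE]
    if (!nrow(wide)) return(NULL)
    defs <- registry[registry$form_id == form, ]
    purrr::map_dfr(seq_len(nrow(defs)), function(i) {
      hits <- eval_check(wide, defs[i, ])
      if (!nrow(hits)) return(NULL)
      tibble(
        subject_id = wide$subject_id[hits$.row],
        site_id = wide$site_id[hits$.row],
        cohort = wide$cohort[hits$.row],
        domain = schema$forms$domain[schema$forms$form_id == form],
        form_id = form,
        visit = wide$visit[hits$.row],
        check_id = defs$check_id[i],
        kind = defs$kind[i],
        fields = hits$fields,
        values = hits$values,
        flag_date = wide$entry_timestamp[hits$.row],
        delivery_instrument = wide$delivery_instrument[hits$.row],
        message = defs$message[i]
      )
    })
  })
  if (!nrow(flags)) {
    flags <- tibble(
      subject_id = character(), site_id = character(), cohort = character(),
      domain = character(), form_id = character(), visit = character(),
      check_id = character(), kind = character(), fields = character(),
      values = character(), flag_date = as.Date(character()),
      delivery_instrument = character(), message = character()
    )
  }
  flags |>
    arrange(.data$site_id, .data$subject_id,
            match(.data$visit, schema$visits$visit), .data$check_id)
}

#' Default check registry for the example schema
#'
#' Encodes one check per exemplar rule family per CRF domain (conditional
#' surgical-site pain after a resting-state scan, cuff-pain duplicate-entry
#' mismatch, PPT remote-site mismatch and performed-vs-entered location,
#' initial pain-rating mismatch, unspecified not-completed reason,
#' vaccination-information missingness, blood draw/centrifuge/freezer
#' chronology) plus required-field missingness for every form and a range
#' check on the first GAD-7 item. Fields referenced by different checks on
#' the same form are disjoint, so any single data perturbation trips
#' exactly one check — the property the simulator's ground-truth
#' injection log relies on.
#'
#' @param schema A [study_schema()]; defaults to [example_study_schema()].
#' @return A check registry tibble.
#' @export
default_check_registry <- function(schema = example_study_schema()) {
  registry <- bind_rows(
    check_definition("imaging_core_missing", "imaging", "missingness",
                     fields = c("scan_date", "scanner_id", "rs_scan"),
                     message = "missing required imaging fields"),
    check_definition("imaging_surgsite_conditional", "imaging",
                     "conditional_missingness",
                     trigger_field = "rs_scan", trigger_value = "yes",
                     dependent_fields = "surgsite_pain",
                     message = "resting-state scan performed but surgical-site pain missing"),
    check_definition("imaging_cuff_mismatch", "imaging", "pair_mismatch",
                     field_a = "cuff_pain_first", field_b = "cuff_pain_second",
                     tolerance = 0,
                     message = "mismatched mid-scan cuff pain ratings"),
    check_definition("qst_core_missing", "qst", "missingness",
                     fields = "qst_date", message = "missing required QST fields"),
    check_definition("qst_ppt_mismatch", "qst", "pair_mismatch",
                     field_a = "ppt_remote_first", field_b = "ppt_remote_second",
                     tolerance = 0.5,
                     message = "mismatched remote-site PPT ratings"),
    check_definition("qst_ppt_location", "qst", "location_mismatch",
                     performed_field = "ppt_site_performed",
                     entered_field = "ppt_site_entered",
                     message = "PPT performed at one site but entered for the other"),
    check_definition("ft_core_missing", "functional_testing", "missingness",
                     fields = "ft_date",
                     message = "missing required functional-testing fields"),
    check_definition("ft_pain_mismatch", "functional_testing", "pair_mismatch",
                     field_a = "pain_rating_first", field_b = "pain_rating_second",
                     tolerance = 0,
                     message = "discrepant first and second initial pain ratings"),
    check_definition("ft_reason_unspecified", "functional_testing",
                     "reason_unspecified",
                     completed_field = "test_completed",
                     reason_field = "test_incomplete_reason",
                     message = "test not completed and no reason specified"),
    check_definition("blood_core_missing", "blood_collection", "missingness",
                     fields = c("collection_date", "vaccination_info"),
                     message = "missing vaccination or collection information"),
    check_definition("blood_chronology", "blood_collection", "chronology",
                     fields = c("draw_time", "centrifuge_time", "freezer_time"),
                     message = "blood draw/centrifuge/freezer times out of order"),
    check_definition("gad7_missing", "gad7", "missingness",
                     fields = paste0("gad7_", 1:7),
                     message = "missing GAD-7 item(s)"),
    check_definition("gad7_item_range", "gad7", "range",
                     field = "gad7_1", min = 0, max = 3,
                     message = "GAD-7 item outside 0-3"),
    check_definition("phq9_missing", "phq9", "missingness",
                     fields = paste0("phq9_", 1:9),
                     message = "missing PHQ-9 item(s)")
  )
  validate_registry(registry, schema)
}
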