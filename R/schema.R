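#' Construct a study schema
#'
#' A study schema describes the fixed design of a multi-site longitudinal
#' study: recruiting sites grouped into multisite clinical centers (MCCs),
#' surgical cohorts, the visit schedule, and the case report forms (CRFs)
#' and patient-reported outcomes (PROs) collected at each visit, down to the
#' individual fields. Every other component of the package (record ingest,
#' the check engine, status classification, the simulator) is driven by a
#' schema.
#'
#' @param sites Data frame with columns `site_id` and `center`
#'   (`"MCC1"`/`"MCC2"`). Site identifiers must be unique.
#' @param cohorts Character vector of cohort labels; defaults to the two
#'   surgical cohorts `"TKA"` (total knee arthroplasty) and `"thoracic"`.
#' @param visits Data frame with columns `visit` (name) and `day_offset`
#'   (nominal days from baseline). Offsets must be strictly increasing and
#'   the first visit must be baseline with offset 0.
#' @param forms Data frame with one row per form: `form_id`, `kind`
#'   (`"CRF"` or `"PRO"`), `domain` (e.g. `"Imaging"`, `"QST"`,
#'   `"FunctionalTesting"`, `"BloodCollection"`, or a PRO name),
#'   `status_field` (the REDCap-style form-completion variable; auto-filled
#'   as `<form_id>_complete` when `NA`), and list-columns `cohorts` and
#'   `visits` giving the applicability predicate (which cohort x visit
#'   combinations the form is collected in; `NULL` entries mean "all").
#' @param fields Data frame with one row per field: `form_id`, `field_name`
#'   (globally unique, REDCap convention), `value_type` (one of `numeric`,
#'   `categorical`, `date`, `time`, `text`, `status`), `choices`
#'   (list-column of allowed values for categorical fields), `range_min`,
#'   `range_max` (for numeric fields), `required` (logical).
#'
#' @return An object of class `study_schema`.
#' @seealso [example_study_schema()] for a ready-made two-center schema,
#'   [applicable_forms()], [load_dictionary()].
#' @export
study_schema <- function(sites, cohorts = c("TKA", "thoracic"), visits, forms, fields) {
  sites <- as_tibble(sites)
  visits <- as_tibble(visits)
  forms <- as_tibble(forms)
  fields <- as_tibble(fields)

  if (anyDuplicated(sites$site_id)) stop_crfqa("site identifiers must be unique")
  if (nrow(visits) < 1 || visits$day_offset[1] != 0) {
    stop_crfqa("the first visit must be baseline with day_offset 0")
  }
  if (any(diff(visits$day_offset) <= 0)) {
    stop_crfqa("visit day offsets must be strictly increasing")
  }
  if (anyDuplicated(fields$field_name)) {
    stop_crfqa(
      "duplicate field_name: %s",
      paste(unique(fields$field_name[duplicated(fields$field_name)]), collapse = ", ")
    )
  }

  if (!"status_field" %in% names(forms)) forms$status_field <- NA_character_
  forms <- forms |>
    mutate(status_field = if_else(
      is.na(.data$status_field), paste0(.data$form_id, "_complete"), .data$status_field
    ))
  if (!"cohorts" %in% names(forms)) forms$cohorts <- list(NULL)
  if (!"visits" %in% names(forms)) forms$visits <- list(NULL)

  # Auto-append a status field row for forms whose dictionary lacks one.
  missing_status <- setdiff(forms$status_field, fields$field_name)
  if (length(missing_status)) {
    fields <- bind_rows(fields, tibble(
      form_id = forms$form_id[match(missing_status, forms$status_field)],
      field_name = missing_status,
      value_type = "status",
      choices = list(c("0", "1", "2")),
      range_min = NA_real_, range_max = NA_real_,
      required = FALSE
    ))
  }

  for (i in seq_len(nrow(forms))) {
    own <- fields$field_name[fields$form_id == forms$form_id[i]]
    if (length(setdiff(own, forms$status_field[i])) == 0) {
      stop_crfqa("form '%s' declares no fields", forms$form_id[i])
    }
    fv <- forms$visits[[i]]
    if (!is.null(fv) && !any(fv %in% visits$visit)) {
      stop_crfqa("form '%s' is applicable to no scheduled visit", forms$form_id[i])
    }
  }

  structure(
    list(sites = sites, cohorts = cohorts, visits = visits,
         forms = forms, fields = fields),
    class = "study_schema"
  )
}

#' @export
print.study_schema <- function(x, ...) {
  cat(sprintf(
    "<study_schema> %d sites (%s), cohorts: %s\n  visits: %s\n  forms: %s\n",
    nrow(x$sites), paste(unique(x$sites$center), collapse = "/"),
    paste(x$cohorts, collapse = ", "),
    paste(sprintf("%s(d%d)", x$visits$visit, x$visits$day_offset), collapse = ", "),
    paste(x$forms$form_id, collapse = ", ")
  ))
  invisible(x)
}

#' Forms collected for a cohort at a visit
#'
#' Applies each form's applicability predicate. The complement of the
#' returned set defines the forms that are "not collected by design" for
#' that cohort/visit (shown yellow in status grids).
#'
#' @param schema A [study_schema()].
#' @param cohort Cohort label.
#' @param visit Visit name (must exist in the schema).
#' @return Character vector of applicable `form_id`s.
#' @export
applicable_forms <- function(schema, cohort, visit) {
  if (!visit %in% schema$visits$visit) {
    stop_crfqa("unknown visit '%s' (schema visits: %s)", visit,
               paste(schema$visits$visit, collapse = ", "))
  }
  keep <- purrr::map_lgl(seq_len(nrow(schema$forms)), function(i) {
    fc <- schema$forms$cohorts[[i]]
    fv <- schema$forms$visits[[i]]
    (is.null(fc) || cohort %in% fc) && (is.null(fv) || visit %in% fv)
  })
  schema$forms$form_id[keep]
}

# Applicability as a full grid: one row per (cohort, visit, form_id) that is
# collected by design. Used by status classification and the simulator.
applicability_grid <- function(schema) {
  tidyr::expand_grid(cohort = schema$cohorts, visit = schema$visits$visit) |>
    mutate(form_id = purrr::map2(
      .data$cohort, .data$visit, ~ applicable_forms(schema, .x, .y)
    )) |>
    tidyr::unnest("form_id")
}

#' Delivery instrument for a form at a site
#'
#' PROs are delivered remotely: MCC1 sites use the REDCap survey system and
#' MCC2 sites use the MyDataHelps app. CRFs are collected in person by
#' research staff regardless of center.
#'
#' @param schema A [study_schema()].
#' @param site_id Vector of site identifiers.
#' @param form_id Vector of form identifiers (recycled against `site_id`).
#' @return Character vector: `"REDCap"`, `"MyDataHelps"` or `"in-person"`.
#' @export
delivery_instrument <- function(schema, site_id, form_id) {
  center <- schema$sites$center[match(site_id, schema$sites$site_id)]
  kind <- schema$forms$kind[match(form_id, schema$forms$form_id)]
  dplyr::case_when(
    kind == "PRO" & center == "MCC1" ~ "REDCap",
    kind == "PRO" & center == "MCC2" ~ "MyDataHelps",
    .default = "in-person"
  )
}

#' Example two-center study schema
#'
#' A compact but fully featured schema emulating a two-MCC, two-cohort
#' post-surgical pain study: four in-person CRF domains (imaging, QST,
#' functional testing, blood collection) and two PRO questionnaires (GAD-7
#' anxiety, PHQ-9 depression), collected at baseline, post-op, 3-month and
#' 6-month visits. PROs are collected at baseline and the 3-/6-month
#' follow-ups only; imaging is restricted to baseline and 6 months, and the
#' functional-testing battery is collected in the TKA cohort only, so that
#' "not collected by design" states occur.
#'
#' @param n_sites_per_center Number of recruiting sites per center
#'   (default 2).
#' @return A [study_schema()].
#' @export
example_study_schema <- function(n_sites_per_center = 2) {
  sites <- tibble(
    site_id = c(paste0("S1", seq_len(n_sites_per_center)),
                paste0("S2", seq_len(n_sites_per_center))),
    center = rep(c("MCC1", "MCC2"), each = n_sites_per_center)
  )
  visits <- tibble(
    visit = c("baseline", "postop", "month3", "month6"),
    day_offset = c(0L, 14L, 90L, 180L)
  )
  forms <- tibble(
    form_id = c("imaging", "qst", "functional_testing", "blood_collection",
                "gad7", "phq9"),
    kind = c("CRF", "CRF", "CRF", "CRF", "PRO", "PRO"),
    domain = c("Imaging", "QST", "FunctionalTesting", "BloodCollection",
               "GAD-7", "PHQ-9"),
    status_field = NA_character_,
    cohorts = list(NULL, NULL, "TKA", NULL, NULL, NULL),
    visits = list(c("baseline", "month6"), NULL, NULL, NULL,
                  c("baseline", "month3", "month6"),
                  c("baseline", "month3", "month6"))
  )

  fld <- function(form, name, type, choices = NULL, lo = NA, hi = NA, req = FALSE) {
    tibble(form_id = form, field_name = name, value_type = type,
           choices = list(choices), range_min = as.numeric(lo),
           range_max = as.numeric(hi), required = req)
  }
  fields <- bind_rows(
    # Imaging: resting-state scan trigger + dependent surgical-site pain,
    # duplicate-entry cuff pain ratings from the personalized-pressure scan.
    fld("imaging", "scan_date", "date", req = TRUE),
    fld("imaging", "scanner_id", "categorical", c("scanner_a", "scanner_b"), req = TRUE),
    fld("imaging", "rs_scan", "categorical", c("yes", "no"), req = TRUE),
    fld("imaging", "surgsite_pain", "numeric", lo = 0, hi = 10),
    fld("imaging", "cuff_pain_first", "numeric", lo = 0, hi = 10),
    fld("imaging", "cuff_pain_second", "numeric", lo = 0, hi = 10),
    # QST: pressure pain threshold (PPT) duplicate entries at the remote
    # body site, plus performed-vs-entered site designators.
    fld("qst", "qst_date", "date", req = TRUE),
    fld("qst", "ppt_remote_first", "numeric", lo = 0, hi = 100),
    fld("qst", "ppt_remote_second", "numeric", lo = 0, hi = 100),
    fld("qst", "ppt_site_performed", "categorical", c("remote", "index")),
    fld("qst", "ppt_site_entered", "categorical", c("remote", "index")),
    # Functional testing: duplicate initial pain ratings and a
    # completion/reason pair.
    fld("functional_testing", "ft_date", "date", req = TRUE),
    fld("functional_testing", "pain_rating_first", "numeric", lo = 0, hi = 10),
    fld("functional_testing", "pain_rating_second", "numeric", lo = 0, hi = 10),
    fld("functional_testing", "test_completed", "categorical", c("yes", "no")),
    fld("functional_testing", "test_incomplete_reason", "text"),
    # Blood collection: vaccination info + processing chronology.
    fld("blood_collection", "collection_date", "date", req = TRUE),
    fld("blood_collection", "vaccination_info", "categorical",
        c("up_to_date", "not_up_to_date", "declined"), req = TRUE),
    fld("blood_collection", "draw_time", "time"),
    fld("blood_collection", "centrifuge_time", "time"),
    fld("blood_collection", "freezer_time", "time"),
    # PROs: item banks (0-3 Likert), all required.
    purrr::map_dfr(1:7, ~ fld("gad7", paste0("gad7_", .x), "numeric",
                              lo = 0, hi = 3, req = TRUE)),
    purrr::map_dfr(1:9, ~ fld("phq9", paste0("phq9_", .x), "numeric",
                              lo = 0, hi = 3, req = TRUE))
  )

  study_schema(sites = sites, visits = visits, forms = forms, fields = fields)
}
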