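#' @importFrom readr read_csv write_csv cols col_character
NULL

# Reserved columns of the flat export that are subject/event metadata, not
# schema fields. Entry-date columns are "<form_id>_entrydate".
RESERVED_COLS <- c("record_id", "redcap_event_name", "site_id", "cohort")

new_violation <- function(location, rule, detail) {
  tibble(location = location, rule = rule, detail = detail)
}

#' Schema violations recorded during ingest
#'
#' Ingest never silently drops or repairs bad input: every anomaly
#' (uncoercible value, unknown column, out-of-choice category) is kept as a
#' violation record attached to the returned table, and the count is
#' reported via a message.
#'
#' @param x A table returned by [load_records()] or [load_dictionary()].
#' @return Tibble with columns `location`, `rule`, `detail` (zero rows when
#'   ingest was clean).
#' @export
schema_violations <- function(x) {
  attr(x, "violations") %||% new_violation(character(), character(), character())
}

encode_applicability <- function(cohorts, visits) {
  parts <- character()
  if (!is.null(cohorts)) parts <- c(parts, paste0("cohorts=", paste(cohorts, collapse = ",")))
  if (!is.null(visits)) parts <- c(parts, paste0("visits=", paste(visits, collapse = ",")))
  if (!length(parts)) "all" else paste(parts, collapse = ";")
}

decode_applicability <- function(s) {
  if (is.na(s) || s == "" || s == "all") {
    return(list(cohorts = NULL, visits = NULL))
  }
  out <- list(cohorts = NULL, visits = NULL)
  for (part in strsplit(s, ";", fixed = TRUE)[[1]]) {
    kv <- strsplit(part, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2 || !kv[1] %in% c("cohorts", "visits")) {
      stop_crfqa("malformed applicability '%s' (expect 'all' or 'cohorts=..;visits=..')", s)
    }
    out[[kv[1]]] <- strsplit(kv[2], ",", fixed = TRUE)[[1]]
  }
  out
}

encode_choices_or_range <- function(fields) {
  purrr::map_chr(seq_len(nrow(fields)), function(i) {
    if (fields$value_type[i] %in% c("categorical", "status")) {
      paste(fields$choices[[i]], collapse = "|")
    } else if (fields$value_type[i] == "numeric" && !is.na(fields$range_min[i])) {
      paste0(fields$range_min[i], "..", fields$range_max[i])
    } else {
      ""
    }
  })
}

#' Write a data dictionary CSV
#'
#' Emits the REDCap-style dictionary dialect read back by
#' [load_dictionary()]: one row per field with columns `field_name`,
#' `form_name`, `field_type`, `choices_or_range`, `required`,
#' `applicability`, plus `form_kind` and `domain` carried on every row of a
#' form so the dictionary round-trips the schema's form metadata.
#'
#' @param schema A [study_schema()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(schema, path) {
  f <- schema$forms
  d <- schema$fields |>
    mutate(
      choices_or_range = encode_choices_or_range(schema$fields),
      required = if_else(.data$required, "y", ""),
      form_name = .data$form_id,
      field_type = .data$value_type
    ) |>
    left_join(
      f |> mutate(applicability = purrr::map2_chr(.data$cohorts, .data$visits,
                                                  encode_applicability)) |>
        select("form_id", form_kind = "kind", "domain", "applicability"),
      by = "form_id"
    ) |>
    select("field_name", "form_name", "field_type", "choices_or_range",
           "required", "applicability", "form_kind", "domain")
  # Preserve form order as declared in the schema.
  d <- d[order(match(d$form_name, f$form_id)), ]
  write_csv(d, path, na = "")
  invisible(path)
}

#' Load a data dictionary CSV into a study schema
#'
#' Parses the dictionary dialect written by [write_dictionary()] (and any
#' CSV with at least `field_name`, `form_name`, `field_type` columns). Forms
#' without a declared status field get `<form>_complete` appended
#' automatically, mirroring the REDCap convention of a per-form completion
#' variable coded 0 = incomplete, 1 = unverified, 2 = complete.
#'
#' The dictionary describes forms and fields only; the study layout (sites,
#' visit schedule, cohorts) is passed separately and defaults to the layout
#' of [example_study_schema()].
#'
#' @param path Dictionary CSV path.
#' @param sites,visits,cohorts Study layout; see [study_schema()].
#' @return A [study_schema()].
#' @export
load_dictionary <- function(path,
                            sites = example_study_schema()$sites,
                            visits = example_study_schema()$visits,
                            cohorts = c("TKA", "thoracic")) {
  if (!file.exists(path)) stop_crfqa("dictionary file not found: %s", path)
  d <- read_csv(path, col_types = cols(.default = col_character()),
                progress = FALSE, show_col_types = FALSE)
  mandatory <- c("field_name", "form_name", "field_type")
  miss <- setdiff(mandatory, names(d))
  if (length(miss)) {
    stop_crfqa("dictionary is missing mandatory column(s): %s",
               paste(miss, collapse = ", "))
  }
  if (anyDuplicated(d$field_name)) {
    stop_crfqa("duplicate field_name in dictionary: %s",
               paste(unique(d$field_name[duplicated(d$field_name)]), collapse = ", "))
  }
  if (!"choices_or_range" %in% names(d)) d$choices_or_range <- ""
  if (!"required" %in% names(d)) d$required <- ""
  if (!"applicability" %in% names(d)) d$applicability <- "all"
  if (!"form_kind" %in% names(d)) d$form_kind <- "CRF"
  if (!"domain" %in% names(d)) d$domain <- d$form_name
  d <- d |> mutate(across(everything(), ~ tidyr::replace_na(.x, "")))

  cr <- d$choices_or_range
  is_range <- grepl("^-?[0-9.]+\\.\\.-?[0-9.]+$", cr)
  fields <- tibble(
    form_id = d$form_name,
    field_name = d$field_name,
    value_type = d$field_type,
    choices = purrr::map2(cr, d$field_type, function(x, ty) {
      if (ty %in% c("categorical", "status") && nzchar(x)) {
        strsplit(x, "|", fixed = TRUE)[[1]]
      } else NULL
    }),
    range_min = if_else(is_range, as_num(sub("\\.\\..*$", "", cr)), NA_real_),
    range_max = if_else(is_range, as_num(sub("^.*\\.\\.", "", cr)), NA_real_),
    required = d$required %in% c("y", "yes", "TRUE", "true", "1")
  )

  form_rows <- d |> distinct(.data$form_name, .keep_all = TRUE)
  status_rows <- d |> filter(.data$field_type == "status")
  forms <- tibble(
    form_id = form_rows$form_name,
    kind = form_rows$form_kind,
    domain = form_rows$domain,
    status_field = status_rows$field_name[
      match(form_rows$form_name, status_rows$form_name)],
    cohorts = purrr::map(form_rows$applicability,
                         ~ decode_applicability(.x)$cohorts),
    visits = purrr::map(form_rows$applicability,
                        ~ decode_applicability(.x)$visits)
  )

  study_schema(sites = sites, cohorts = cohorts, visits = visits,
               forms = forms, fields = fields)
}

#' Save / load a full schema as a structured config file
#'
#' Unlike the dictionary CSV, the YAML config captures the complete schema
#' (sites, cohorts, visit schedule, forms, fields) and round-trips it
#' exactly.
#'
#' @param schema A [study_schema()].
#' @param path YAML file path.
#' @return `write_schema_config()` returns `path` invisibly;
#'   `load_schema_config()` returns a [study_schema()].
#' @export
write_schema_config <- function(schema, path) {
  cfg <- list(
    sites = purrr::pmap(schema$sites, list),
    cohorts = as.list(schema$cohorts),
    visits = purrr::pmap(schema$visits, list),
    forms = purrr::pmap(schema$forms, function(form_id, kind, domain,
                                               status_field, cohorts, visits) {
      list(form_id = form_id, kind = kind, domain = domain,
           status_field = status_field,
           cohorts = if (is.null(cohorts)) "all" else as.list(cohorts),
           visits = if (is.null(visits)) "all" else as.list(visits))
    }),
    fields = purrr::pmap(schema$fields, function(form_id, field_name, value_type,
                                                 choices, range_min, range_max,
                                                 required) {
      list(form_id = form_id, field_name = field_name, value_type = value_type,
           choices = if (is.null(choices)) list() else as.list(choices),
           range_min = if (is.na(range_min)) NULL else range_min,
           range_max = if (is.na(range_max)) NULL else range_max,
           required = required)
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_schema_config
#' @export
load_schema_config <- function(path) {
  if (!file.exists(path)) stop_crfqa("schema config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  unall <- function(x) if (identical(x, "all") || is.null(x)) NULL else unlist(x)
  study_schema(
    sites = purrr::map_dfr(cfg$sites, as_tibble),
    cohorts = unlist(cfg$cohorts),
    visits = purrr::map_dfr(cfg$visits, as_tibble),
    forms = tibble(
      form_id = purrr::map_chr(cfg$forms, "form_id"),
      kind = purrr::map_chr(cfg$forms, "kind"),
      domain = purrr::map_chr(cfg$forms, "domain"),
      status_field = purrr::map_chr(cfg$forms, "status_field"),
      cohorts = purrr::map(cfg$forms, ~ unall(.x$cohorts)),
      visits = purrr::map(cfg$forms, ~ unall(.x$visits))
    ),
    fields = tibble(
      form_id = purrr::map_chr(cfg$fields, "form_id"),
      field_name = purrr::map_chr(cfg$fields, "field_name"),
      value_type = purrr::map_chr(cfg$fields, "value_type"),
      choices = purrr::map(cfg$fields, ~ if (length(.x$choices)) unlist(.x$choices) else NULL),
      range_min = purrr::map_dbl(cfg$fields, ~ .x$range_min %||% NA_real_),
      range_max = purrr::map_dbl(cfg$fields, ~ .x$range_max %||% NA_real_),
      required = purrr::map_lgl(cfg$fields, "required")
    )
  )
}

# Value-format validators per declared type; return TRUE for conforming
# non-missing values.
value_conforms <- function(value, value_type, choices) {
  switch(value_type,
    numeric = !is.na(as_num(value)),
    date = grepl("^\\d{4}-\\d{2}-\\d{2}$", value) &
      !is.na(suppressWarnings(as.Date(value, format = "%Y-%m-%d"))),
    time = grepl("^([01][0-9]|2[0-3]):[0-5][0-9]$", value),
    categorical = ,
    status = if (is.null(choices)) TRUE else value %in% choices,
    TRUE # text
  )
}

#' Melt a wide export into tidy observation records
#'
#' Converts the flat one-row-per-subject-per-event table into the tidy
#' contract used everywhere downstream: one record per (subject, visit,
#' form, field), each cell a single value. Values stay character-typed with
#' `""` mapped to `NA`; values that do not conform to the field's declared
#' type are *kept* verbatim and reported as schema violations, never
#' silently dropped or repaired.
#'
#' @param wide Data frame with columns `record_id`, `redcap_event_name`,
#'   `site_id`, `cohort`, per-form `<form>_entrydate` columns, and one
#'   column per field.
#' @param schema A [study_schema()].
#' @return Tidy tibble (`subject_id`, `site_id`, `cohort`, `visit`,
#'   `form_id`, `field_name`, `value`, `entry_timestamp`,
#'   `delivery_instrument`) with a `violations` attribute; see
#'   [schema_violations()].
#' @export
as_tidy_records <- function(wide, schema) {
  wide <- as_tibble(wide) |> mutate(across(everything(), as.character))
  miss <- setdiff(RESERVED_COLS, names(wide))
  if (length(miss)) {
    stop_crfqa("records table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  dup <- duplicated(wide[c("record_id", "redcap_event_name")])
  if (any(dup)) {
    stop_crfqa("duplicate (record_id, redcap_event_name) rows: %s",
               paste(utils::head(wide$record_id[dup], 5), collapse = ", "))
  }
  unknown_events <- setdiff(unique(wide$redcap_event_name), schema$visits$visit)
  if (length(unknown_events)) {
    stop_crfqa("events not in schema visit schedule: %s",
               paste(unknown_events, collapse = ", "))
  }

  entry_cols <- paste0(schema$forms$form_id, "_entrydate")
  known <- c(RESERVED_COLS, entry_cols, schema$fields$field_name)
  violations <- list()
  extra <- setdiff(names(wide), known)
  if (length(extra)) {
    violations <- c(violations, list(new_violation(
      paste0("column ", extra), "unknown_column",
      sprintf("column '%s' is not in the schema; ignored", extra)
    )))
    warning(sprintf("ignoring %d unknown column(s): %s", length(extra),
                    paste(extra, collapse = ", ")), call. = FALSE)
  }

  field_cols <- intersect(schema$fields$field_name, names(wide))
  tidy <- wide |>
    select(all_of(c(RESERVED_COLS, intersect(entry_cols, names(wide)), field_cols))) |>
    tidyr::pivot_longer(all_of(field_cols), names_to = "field_name",
                        values_to = "value") |>
    mutate(value = if_else(is_blank(.data$value), NA_character_, .data$value)) |>
    left_join(schema$fields |> select("field_name", "form_id", "value_type", "choices"),
              by = "field_name")

  # Per-record entry timestamp comes from the form's entry-date column.
  entry_long <- wide |>
    select(all_of(c("record_id", "redcap_event_name",
                    intersect(entry_cols, names(wide))))) |>
    tidyr::pivot_longer(-all_of(c("record_id", "redcap_event_name")),
                        names_to = "form_id", values_to = "entry_timestamp") |>
    mutate(form_id = sub("_entrydate$", "", .data$form_id),
           entry_timestamp = as.Date(.data$entry_timestamp))
  tidy <- tidy |>
    left_join(entry_long, by = c("record_id", "redcap_event_name", "form_id"))

  # Type-conformance audit (kept values, reported violations).
  bad <- tidy |>
    filter(!is.na(.data$value)) |>
    filter(!purrr::pmap_lgl(list(.data$value, .data$value_type, .data$choices),
                            value_conforms))
  if (nrow(bad)) {
    violations <- c(violations, list(new_violation(
      sprintf("record %s/%s, col %s", bad$record_id, bad$redcap_event_name,
              bad$field_name),
      "uncoercible_value",
      sprintf("value '%s' does not conform to declared type '%s'",
              bad$value, bad$value_type)
    )))
  }

  out <- tidy |>
    transmute(
      subject_id = .data$record_id,
      site_id = .data$site_id,
      cohort = .data$cohort,
      visit = .data$redcap_event_name,
      form_id = .data$form_id,
      field_name = .data$field_name,
      value = .data$value,
      entry_timestamp = .data$entry_timestamp,
      delivery_instrument = delivery_instrument(schema, .data$site_id, .data$form_id)
    ) |>
    arrange(.data$site_id, .data$subject_id,
            match(.data$visit, schema$visits$visit),
            match(.data$form_id, schema$forms$form_id),
            match(.data$field_name, schema$fields$field_name))

  stopifnot(!anyDuplicated(out[c("subject_id", "visit", "form_id", "field_name")]))
  viol <- if (length(violations)) bind_rows(violations) else
    new_violation(character(), character(), character())
  attr(out, "violations") <- viol
  if (nrow(viol)) message(sprintf("ingest recorded %d schema violation(s)", nrow(viol)))
  out
}

#' Read a flat records export
#'
#' Reads the simplified REDCap flat-export dialect (columns `record_id`,
#' `redcap_event_name`, `site_id`, `cohort`, then field columns; one row per
#' subject x event; blanks are missing) and melts it into tidy observation
#' records via [as_tidy_records()].
#'
#' @param path Records CSV path.
#' @param schema A [study_schema()].
#' @return Tidy record tibble; see [as_tidy_records()].
#' @export
load_records <- function(path, schema) {
  if (!file.exists(path)) stop_crfqa("records file not found: %s", path)
  wide <- read_csv(path, col_types = cols(.default = col_character()),
                   progress = FALSE, show_col_types = FALSE)
  as_tidy_records(wide, schema)
}

#' Write a flat records export
#'
#' @param wide Wide records table (as produced by [simulate_study()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(wide, path) {
  write_csv(wide, path, na = "")
  invisible(path)
}
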