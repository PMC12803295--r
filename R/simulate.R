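minutes_to_hm <- function(m) sprintf("%02d:%02d", m %/% 60, m %% 60)

#' Configure a synthetic study
#'
#' Collects everything the simulator needs: the schema and check registry,
#' the enrollment pattern, the observation window, and the error-injection
#' model. Defaults describe a compact two-center post-surgical pain study
#' observed over 18 months (2024-03 to 2025-09) with steady enrollment.
#'
#' Error injection is per check: a completed form instance entered in study
#' month `m` receives a violation of check `c` with probability
#' `p_c * (1 - r)^m`, where `p_c` is the check's baseline probability and
#' `r` the monthly decay factor (emulating error rates falling as sites
#' receive feedback). PRO missingness probabilities can be set per delivery
#' instrument to study instrument effects.
#'
#' @param seed Master seed; fixes all randomness end-to-end.
#' @param schema A [study_schema()].
#' @param registry Check registry evaluated and injected against.
#' @param study_start First enrollment month (Date or string).
#' @param as_of Snapshot date: visits after it have not happened yet.
#' @param enrollment_per_site_per_month New subjects per site per month.
#' @param months_enrollment Number of enrolling months.
#' @param cohort_mix Named probabilities over the schema cohorts.
#' @param injection_probability Baseline per-check injection probability:
#'   a single number or a named vector keyed by `check_id`.
#' @param monthly_decay Decay factor `r` in `[0, 1)`.
#' @param pro_missingness Named per-instrument missingness probabilities
#'   for PRO forms (names `REDCap`, `MyDataHelps`).
#' @param incomplete_probability Probability a form instance is left
#'   incomplete/unverified (status 0 or 1).
#' @param unknown_probability Probability the status field is left blank.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              schema = example_study_schema(),
                              registry = default_check_registry(schema),
                              study_start = "2024-03-01",
                              as_of = "2025-09-01",
                              enrollment_per_site_per_month = 4,
                              months_enrollment = 14,
                              cohort_mix = c(TKA = 0.6, thoracic = 0.4),
                              injection_probability = 0.05,
                              monthly_decay = 0,
                              pro_missingness = c(REDCap = 0.05, MyDataHelps = 0.05),
                              incomplete_probability = 0.08,
                              unknown_probability = 0.03) {
  probs <- c(injection_probability, pro_missingness, incomplete_probability,
             unknown_probability)
  if (any(probs < 0 | probs > 1)) stop_crfqa("probabilities must lie in [0, 1]")
  if (monthly_decay < 0 || monthly_decay >= 1) {
    stop_crfqa("monthly_decay must lie in [0, 1)")
  }
  if (!setequal(names(cohort_mix), schema$cohorts)) {
    stop_crfqa("cohort_mix must name exactly the schema cohorts (%s)",
               paste(schema$cohorts, collapse = ", "))
  }
  validate_registry(registry, schema)
  structure(
    list(seed = seed, schema = schema, registry = registry,
         study_start = as.Date(study_start), as_of = as.Date(as_of),
         enrollment_per_site_per_month = enrollment_per_site_per_month,
         months_enrollment = months_enrollment, cohort_mix = cohort_mix,
         injection_probability = injection_probability,
         monthly_decay = monthly_decay, pro_missingness = pro_missingness,
         incomplete_probability = incomplete_probability,
         unknown_probability = unknown_probability),
    class = "simulation_config"
  )
}

# Baseline injection probability per check: PRO missingness checks draw
# from the per-instrument table, everything else from the (possibly
# check_id-named) injection_probability.
check_base_probs <- function(config) {
  form_kind <- stats::setNames(config$schema$forms$kind,
                               config$schema$forms$form_id)
  reg <- config$registry
  p <- config$injection_probability
  base <- purrr::map_dbl(seq_len(nrow(reg)), function(j) {
    if (!is.null(names(p)) && reg$check_id[j] %in% names(p)) {
      unname(p[[reg$check_id[j]]])
    } else {
      unname(p[[1]])
    }
  })
  list(
    base = stats::setNames(base, reg$check_id),
    pro_missing = stats::setNames(
      reg$kind == "missingness" & form_kind[reg$form_id] == "PRO",
      reg$check_id
    )
  )
}

# Clean value for one field, respecting type, choices and range.
# `meta` is a plain list: value_type, range_min, range_max, choices.
gen_field_value <- function(meta, visit_date) {
  switch(meta$value_type,
    numeric = {
      lo <- meta$range_min; hi <- meta$range_max
      if (is.na(lo)) { lo <- 0; hi <- 100 }
      if (lo == round(lo) && hi == round(hi) && hi - lo <= 30) {
        as.character(sample(seq(lo, hi), 1))
      } else {
        sprintf("%.1f", stats::runif(1, lo, hi))
      }
    },
    categorical = sample(meta$choices, 1),
    date = format(visit_date),
    time = minutes_to_hm(sample(420:960, 1)),
    text = sample(c("scheduling conflict", "equipment failure",
                    "staff unavailable", "participant declined"), 1),
    NA_character_
  )
}

# Enforce every check's clean state on a freshly generated instance.
clean_instance <- function(values, defs) {
  for (i in seq_len(nrow(defs))) {
    p <- defs$params[[i]]
    switch(defs$kind[i],
      pair_mismatch = { values[p$field_b] <- values[p$field_a] },
      location_mismatch = { values[p$entered_field] <- values[p$performed_field] },
      chronology = {
        mins <- sort(parse_hm(unlist(values[p$fields])))
        values[p$fields] <- minutes_to_hm(mins)
      },
      conditional_missingness = {
        if (!identical(unname(values[[p$trigger_field]]), p$trigger_value)) {
          values[p$dependent_fields] <- NA_character_
        }
      },
      reason_unspecified = {
        if (!identical(unname(values[[p$completed_field]]), "no")) {
          values[p$reason_field] <- NA_character_
        }
      }
    )
  }
  values
}

# Perturb one instance so that exactly the given check fires. Returns NULL
# when the perturbation would collide with fields already touched by an
# earlier injection on this instance (the injection is then skipped, so the
# log stays exactly equivalent to the realized violations).
perturb_instance <- function(values, def_row, touched) {
  p <- def_row$params[[1]]
  switch(def_row$kind,
    missingness = {
      candidates <- setdiff(p$fields, touched)
      if (!length(candidates)) return(NULL)
      f <- if (length(candidates) == 1) candidates else sample(candidates, 1)
      values[f] <- NA_character_
      list(values = values, fields = f, note = "blanked required field")
    },
    pair_mismatch = {
      if (any(c(p$field_a, p$field_b) %in% touched)) return(NULL)
      if (p$numeric %||% TRUE) {
        delta <- (p$tolerance %||% 0) + sample(1:3, 1)
        values[p$field_b] <- as.character(as_num(values[[p$field_a]]) + delta)
      } else {
        values[p$field_b] <- paste0(values[[p$field_a]], "_alt")
      }
      list(values = values, fields = paste(p$field_a, p$field_b, sep = ","),
           note = "perturbed second entry of pair")
    },
    conditional_missingness = {
      if (any(c(p$trigger_field, p$dependent_fields) %in% touched)) return(NULL)
      values[p$trigger_field] <- p$trigger_value
      values[p$dependent_fields[1]] <- NA_character_
      list(values = values,
           fields = paste(c(p$trigger_field, p$dependent_fields[1]), collapse = ","),
           note = "trigger set, dependent blanked")
    },
    chronology = {
      if (any(p$fields %in% touched)) return(NULL)
      last <- parse_hm(values[[p$fields[length(p$fields)]]])
      values[p$fields[1]] <- minutes_to_hm(min(last + 30, 1439))
      list(values = values,
           fields = paste(p$fields[c(1, length(p$fields))], collapse = ","),
           note = "first time moved after last")
    },
    location_mismatch = {
      if (any(c(p$performed_field, p$entered_field) %in% touched)) return(NULL)
      other <- setdiff(c("remote", "index"), values[[p$performed_field]])
      values[p$entered_field] <- other[1]
      list(values = values,
           fields = paste(p$performed_field, p$entered_field, sep = ","),
           note = "entered site flipped")
    },
    reason_unspecified = {
      if (any(c(p$completed_field, p$reason_field) %in% touched)) return(NULL)
      values[p$completed_field] <- "no"
      values[p$reason_field] <- NA_character_
      list(values = values,
           fields = paste(p$completed_field, p$reason_field, sep = ","),
           note = "not completed, reason blanked")
    },
    range = {
      if (p$field %in% touched) return(NULL)
      values[p$field] <- as.character(p$max + sample(1:5, 1))
      list(values = values, fields = p$field, note = "value pushed out of range")
    }
  )
}

#' Simulate a complete multi-site study with ground-truth error injection
#'
#' Generates a clean study first — enrollment by site and month, cohort
#' assignment, visit-consistent entry dates, in-range values satisfying
#' every check — and then injects violations per check at probability
#' `p * (1 - r)^month`, recording each injected violation in a log that is
#' exactly equivalent to the violations present in the emitted data.
#' Randomness is split into one stream per concern (enrollment, values,
#' injection), each derived from the master seed, so adding draws to one
#' concern leaves the others unchanged.
#'
#' @param config A [simulation_config()].
#' @return A `simulated_study` list: `records` (wide flat-export tibble),
#'   `injection_log`, `schema`, `registry`, `config`. Use
#'   [study_records()] for tidy records and [write_study()] to emit the
#'   CSV dialect that [load_records()]/[load_dictionary()] read back.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  schema <- config$schema
  registry <- config$registry

  # -- stream 1: enrollment ---------------------------------------------
  set.seed(config$seed + 101L)
  subjects <- purrr::map_dfr(schema$sites$site_id, function(site) {
    purrr::map_dfr(seq_len(config$months_enrollment) - 1L, function(m) {
      n <- config$enrollment_per_site_per_month
      if (n == 0) return(NULL)
      tibble(
        site_id = site, enroll_month = m,
        cohort = sample(names(config$cohort_mix), n, replace = TRUE,
                        prob = config$cohort_mix),
        baseline_date = config$study_start %m+%
          lubridate::period(m, "months") + sample(0:27, n, replace = TRUE)
      )
    })
  }) |>
    mutate(subject_id = sprintf("%s-%04d", .data$site_id,
                                stats::ave(seq_along(.data$site_id),
                                           .data$site_id, FUN = seq_along)))

  events <- subjects |>
    tidyr::expand_grid(schema$visits) |>
    mutate(visit_date = .data$baseline_date + .data$day_offset) |>
    filter(.data$visit_date <= config$as_of)

  # -- stream 2: clean values -------------------------------------------
  set.seed(config$seed + 202L)
  status_fields <- schema$forms$status_field
  # plain-list metadata per form, computed once (the loop below is hot)
  form_meta <- stats::setNames(purrr::map(schema$forms$form_id, function(form) {
    ff <- schema$fields[schema$fields$form_id == form &
                          !schema$fields$field_name %in% status_fields, ]
    list(
      fields = purrr::map(seq_len(nrow(ff)), function(i) list(
        value_type = ff$value_type[i], range_min = ff$range_min[i],
        range_max = ff$range_max[i], choices = ff$choices[[i]]
      )) |> stats::setNames(ff$field_name),
      defs = registry[registry$form_id == form, , drop = FALSE]
    )
  }), schema$forms$form_id)
  applicable <- applicability_grid(schema)
  app_key <- split(applicable$form_id, paste(applicable$cohort, applicable$visit))

  instance_rows <- vector("list", nrow(events) * nrow(schema$forms))
  k <- 0L
  for (ei in seq_len(nrow(events))) {
    ev_subject <- events$subject_id[ei]; ev_site <- events$site_id[ei]
    ev_cohort <- events$cohort[ei]; ev_visit <- events$visit[ei]
    ev_date <- events$visit_date[ei]
    forms <- app_key[[paste(ev_cohort, ev_visit)]]
    for (form in forms) {
      meta <- form_meta[[form]]
      values <- vapply(meta$fields, gen_field_value, character(1),
                       visit_date = ev_date)
      values <- clean_instance(values, meta$defs)
      u <- stats::runif(1)
      status <- if (u < config$unknown_probability) NA_character_
        else if (u < config$unknown_probability + config$incomplete_probability)
          sample(c("0", "1"), 1)
        else "2"
      entry <- min(ev_date + sample(0:3, 1), config$as_of)
      k <- k + 1L
      instance_rows[[k]] <- list(
        subject_id = ev_subject, site_id = ev_site, cohort = ev_cohort,
        visit = ev_visit, form_id = form, status = status,
        entry_date = entry, values = values
      )
    }
  }
  instance_rows <- instance_rows[seq_len(k)]

  # -- stream 3: injection ----------------------------------------------
  set.seed(config$seed + 303L)
  site_form_instrument <- tidyr::expand_grid(site_id = schema$sites$site_id,
                                             form_id = schema$forms$form_id)
  site_form_instrument$instrument <- delivery_instrument(
    schema, site_form_instrument$site_id, site_form_instrument$form_id)
  instrument_of <- stats::setNames(
    site_form_instrument$instrument,
    paste(site_form_instrument$site_id, site_form_instrument$form_id))
  probs <- check_base_probs(config)
  months_elapsed <- months_between(
    config$study_start,
    as.Date(purrr::map_dbl(instance_rows, "entry_date"),
            origin = "1970-01-01")
  )
  log_rows <- list()
  for (i in seq_along(instance_rows)) {
    inst <- instance_rows[[i]]
    if (is.na(inst$status) || inst$status != "2") next
    defs <- form_meta[[inst$form_id]]$defs
    if (!nrow(defs)) next
    instrument <- instrument_of[[paste(inst$site_id, inst$form_id)]]
    decay <- (1 - config$monthly_decay)^months_elapsed[i]
    touched <- character()
    for (j in seq_len(nrow(defs))) {
      cid <- defs$check_id[j]
      p0 <- if (probs$pro_missing[[cid]] &&
                instrument %in% names(config$pro_missingness)) {
        unname(config$pro_missingness[[instrument]])
      } else {
        probs$base[[cid]]
      }
      p_eff <- p0 * decay
      if (stats::runif(1) >= p_eff) next
      res <- perturb_instance(inst$values, defs[j, ], touched)
      if (is.null(res)) next
      inst$values <- res$values
      touched <- union(touched, strsplit(res$fields, ",", fixed = TRUE)[[1]])
      log_rows[[length(log_rows) + 1L]] <- list(
        subject_id = inst$subject_id, site_id = inst$site_id,
        cohort = inst$cohort, visit = inst$visit, form_id = inst$form_id,
        check_id = defs$check_id[j], fields = res$fields, note = res$note
      )
    }
    instance_rows[[i]] <- inst
  }
  injection_log <- if (length(log_rows)) {
    purrr::map_dfr(log_rows, as_tibble)
  } else {
    tibble(subject_id = character(), site_id = character(), cohort = character(),
           visit = character(), form_id = character(), check_id = character(),
           fields = character(), note = character())
  }

  # -- assemble the wide flat export ------------------------------------
  status_of <- stats::setNames(schema$forms$status_field, schema$forms$form_id)
  parts <- purrr::map(instance_rows, function(inst) {
    vals <- inst$values
    nm <- c(names(vals), status_of[[inst$form_id]],
            paste0(inst$form_id, "_entrydate"))
    list(record_id = rep(inst$subject_id, length(nm)),
         redcap_event_name = rep(inst$visit, length(nm)),
         site_id = rep(inst$site_id, length(nm)),
         cohort = rep(inst$cohort, length(nm)),
         field_name = nm,
         value = c(unname(vals), inst$status, format(inst$entry_date)))
  })
  inst_tbl <- tibble(
    record_id = unlist(purrr::map(parts, "record_id")),
    redcap_event_name = unlist(purrr::map(parts, "redcap_event_name")),
    site_id = unlist(purrr::map(parts, "site_id")),
    cohort = unlist(purrr::map(parts, "cohort")),
    field_name = unlist(purrr::map(parts, "field_name")),
    value = unlist(purrr::map(parts, "value"))
  )
  wide <- inst_tbl |>
    tidyr::pivot_wider(names_from = "field_name", values_from = "value")
  # fixed, schema-driven column order; absent columns (forms never
  # applicable under this config) are added empty
  all_cols <- c(RESERVED_COLS,
                unlist(purrr::map(schema$forms$form_id, function(f) {
                  c(schema$fields$field_name[schema$fields$form_id == f],
                    paste0(f, "_entrydate"))
                })))
  for (cl in setdiff(all_cols, names(wide))) wide[[cl]] <- NA_character_
  wide <- wide |>
    select(all_of(all_cols)) |>
    arrange(.data$site_id, .data$record_id,
            match(.data$redcap_event_name, schema$visits$visit))

  structure(
    list(records = wide, injection_log = injection_log, schema = schema,
         registry = registry, config = config,
         subjects = subjects |> select("subject_id", "site_id", "cohort",
                                       "baseline_date")),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> %d subjects, %d event rows, %d injected violation(s) (seed %d)\n",
    nrow(x$subjects), nrow(x$records), nrow(x$injection_log), x$config$seed
  ))
  invisible(x)
}

#' Tidy records of a simulated study
#'
#' @param sim A `simulated_study`.
#' @return Tidy record tibble (see [as_tidy_records()]).
#' @export
study_records <- function(sim) {
  suppressMessages(as_tidy_records(sim$records, sim$schema))
}

#' Write a simulated study to disk
#'
#' Emits `records.csv` and `dictionary.csv` in the dialect that
#' [load_records()] and [load_dictionary()] read back, plus
#' `injection_log.csv` (the ground truth) and `schema.yaml`.
#'
#' @param sim A `simulated_study`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    records = file.path(dir, "records.csv"),
    dictionary = file.path(dir, "dictionary.csv"),
    injection_log = file.path(dir, "injection_log.csv"),
    schema = file.path(dir, "schema.yaml")
  )
  write_records(sim$records, paths[["records"]])
  write_dictionary(sim$schema, paths[["dictionary"]])
  write_csv(sim$injection_log, paths[["injection_log"]], na = "")
  write_schema_config(sim$schema, paths[["schema"]])
  invisible(paths)
}

# Table-2-shaped flag series: per-domain first/last month counts fixed,
# geometric interpolation in between.
table2_fixture_spec <- function() {
  tibble(
    domain = c("BloodCollection", "FunctionalTesting", "Imaging", "QST"),
    form_id = c("blood_collection", "functional_testing", "imaging", "qst"),
    check_id = c("blood_chronology", "ft_pain_mismatch",
                 "imaging_cuff_mismatch", "qst_ppt_mismatch"),
    first_date = as.Date(c("2024-08-27", "2024-11-06", "2024-03-13", "2024-08-27")),
    first_count = c(6L, 1L, 16L, 17L),
    last_date = as.Date(c("2025-07-16", "2025-07-16", "2025-08-13", "2025-08-13")),
    last_count = c(2L, 2L, 1L, 1L)
  )
}

#' Replay a named built-in fixture
#'
#' `"table2"` replays a deterministic flag set whose per-domain monthly
#' error series start and end exactly at known anchor months and counts
#' (Imaging 2024-03: 16 flags down to 2025-08: 1; QST 2024-08: 17 down to
#' 2025-08: 1; blood collection 2024-08: 6 down to 2025-07: 2; functional
#' testing 2024-11: 1 up to 2025-07: 2 — 40 initial errors summed across
#' domains falling to 6), with geometrically interpolated counts in
#' between. It anchors the observed-percent-change surface of
#' [trend_summary()] without any simulation.
#'
#' @param name Fixture name; currently `"table2"`.
#' @return List with `flags` (a flag tibble) and `description`. This
#'   fixture ships flags only (`records = NULL`): the trend surface keys on
#'   flags alone.
#' @export
replay_fixture <- function(name) {
  fixtures <- c("table2")
  if (!name %in% fixtures) {
    stop_crfqa("unknown fixture '%s' (available: %s)", name,
               paste(fixtures, collapse = ", "))
  }
  spec <- table2_fixture_spec()
  flags <- purrr::map_dfr(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    span <- months_between(s$first_date, s$last_date)
    months <- seq(month_floor(s$first_date), by = "month", length.out = span + 1)
    # geometric path between the anchor counts; anchors stay exact
    counts <- round(s$first_count *
                      (s$last_count / s$first_count)^(seq(0, span) / span))
    counts[1] <- s$first_count
    counts[span + 1] <- s$last_count
    dates <- c(s$first_date,
               months[seq(2, span)] + 14L,
               s$last_date)
    purrr::map_dfr(seq_along(months), function(mi) {
      n <- counts[mi]
      if (n == 0) return(NULL)
      tibble(
        subject_id = sprintf("fx-%s-%02d-%02d", s$form_id, mi, seq_len(n)),
        site_id = "S11", cohort = "TKA", domain = s$domain,
        form_id = s$form_id, visit = "baseline", check_id = s$check_id,
        kind = "pair_mismatch", fields = "", values = "",
        flag_date = dates[mi], delivery_instrument = "in-person",
        message = "fixture flag"
      )
    })
  })
  list(
    flags = flags, records = NULL,
    description = "Deterministic per-domain monthly error series with fixed first/last anchor counts"
  )
}
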