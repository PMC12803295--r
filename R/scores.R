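#' Define a biomarker score
#'
#' A score definition maps a form's item fields to a single per-instance
#' score via a `sum`, `mean` or `single` (one-field) rule, with a declared
#' valid range.
#'
#' @param form_id Form the score belongs to.
#' @param items Item field names (subset of the form's fields).
#' @param rule `"sum"`, `"mean"` or `"single"`.
#' @param range_min,range_max Valid score range (finite).
#' @return One-row tibble; rows bind into a score-definition table.
#' @export
score_definition <- function(form_id, items, rule = c("sum", "mean", "single"),
                             range_min, range_max) {
  rule <- match.arg(rule)
  if (!is.finite(range_min) || !is.finite(range_max)) {
    stop_crfqa("score range for '%s' must be finite", form_id)
  }
  if (rule == "single" && length(items) != 1) {
    stop_crfqa("'single' rule takes exactly one item field")
  }
  tibble(form_id = form_id, items = list(items), rule = rule,
         range_min = range_min, range_max = range_max)
}

#' Default score definitions for the example schema
#'
#' GAD-7 (7 items, 0-3 each, total 0-21) and PHQ-9 (9 items, 0-3 each,
#' total 0-27), both summed.
#'
#' @return Score-definition tibble.
#' @export
default_score_definitions <- function() {
  bind_rows(
    score_definition("gad7", paste0("gad7_", 1:7), "sum", 0, 21),
    score_definition("phq9", paste0("phq9_", 1:9), "sum", 0, 27)
  )
}

#' Compute per-instance biomarker scores
#'
#' Applies each score rule over its items for every *complete* form
#' instance. Any missing item makes the score missing — no imputation.
#' Scores outside the declared range are kept but flagged as range
#' violations.
#'
#' @param records Tidy records.
#' @param schema A [study_schema()].
#' @param definitions Score definitions (default
#'   [default_score_definitions()]).
#' @return Tibble `subject_id`, `site_id`, `cohort`, `visit`, `form_id`,
#'   `score`, `range_violation`.
#' @export
score_forms <- function(records, schema, definitions = default_score_definitions()) {
  purrr::map_dfr(seq_len(nrow(definitions)), function(i) {
    def <- definitions[i, ]
    items <- def$items[[1]]
    wide <- form_instances(records, schema, def$form_id)
    wide <- wide[!is.na(wide$.status) & wide$.status == "2", , drop = FALSE]
    if (!nrow(wide)) return(NULL)
    vals <- purrr::map(items, ~ as_num(col_or_na(wide, .x)))
    mat <- do.call(cbind, vals)
    score <- switch(def$rule,
      sum = rowSums(mat),
      mean = rowMeans(mat),
      single = mat[, 1]
    )
    tibble(
      subject_id = wide$subject_id, site_id = wide$site_id,
      cohort = wide$cohort, visit = wide$visit, form_id = def$form_id,
      score = score,
      range_violation = !is.na(score) &
        (score < def$range_min | score > def$range_max)
    )
  }) |>
    arrange(.data$form_id, .data$site_id, .data$subject_id, .data$visit)
}

#' Score distribution summaries by visit and cohort
#'
#' Per-group (form x visit x cohort) n, mean, median and quartiles.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7). Groups present in the schema grid but
#' without scores are reported with `n = 0` rather than dropped.
#'
#' @param scores Output of [score_forms()].
#' @param schema A [study_schema()] (supplies the visit x cohort grid).
#' @return Tibble `form_id`, `visit`, `cohort`, `n`, `mean`, `median`,
#'   `q1`, `q3`, `iqr`.
#' @export
distribution_summary <- function(scores, schema) {
  grid <- tidyr::expand_grid(
    form_id = unique(scores$form_id),
    visit = schema$visits$visit,
    cohort = schema$cohorts
  )
  scores |>
    filter(!is.na(.data$score)) |>
    summarise(
      n = dplyr::n(),
      mean = mean(.data$score),
      median = stats::median(.data$score),
      q1 = stats::quantile(.data$score, 0.25, type = 7, names = FALSE),
      q3 = stats::quantile(.data$score, 0.75, type = 7, names = FALSE),
      .by = c("form_id", "visit", "cohort")
    ) |>
    right_join(grid, by = c("form_id", "visit", "cohort")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L), iqr = .data$q3 - .data$q1) |>
    arrange(.data$form_id, match(.data$visit, schema$visits$visit),
            .data$cohort)
}

#' Flag score outliers with Tukey fences
#'
#' Within each form x visit x cohort group of at least 4 scores, flags
#' scores strictly outside \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\] (type-7
#' quantiles). Smaller groups yield no outliers.
#'
#' @param scores Output of [score_forms()].
#' @param min_group_n Minimum group size to evaluate (default 4).
#' @return The flagged score rows, with `lower_fence` and `upper_fence`
#'   columns.
#' @export
flag_outliers <- function(scores, min_group_n = 4) {
  scores |>
    filter(!is.na(.data$score)) |>
    mutate(
      .n = dplyr::n(),
      q1 = stats::quantile(.data$score, 0.25, type = 7, names = FALSE),
      q3 = stats::quantile(.data$score, 0.75, type = 7, names = FALSE),
      .by = c("form_id", "visit", "cohort")
    ) |>
    mutate(lower_fence = .data$q1 - 1.5 * (.data$q3 - .data$q1),
           upper_fence = .data$q3 + 1.5 * (.data$q3 - .data$q1)) |>
    filter(.data$.n >= min_group_n,
           .data$score < .data$lower_fence | .data$score > .data$upper_fence) |>
    select("subject_id", "site_id", "cohort", "visit", "form_id", "score",
           "lower_fence", "upper_fence") |>
    arrange(.data$form_id, .data$site_id, .data$subject_id, .data$visit)
}
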