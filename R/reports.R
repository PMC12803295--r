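REPORT_COLS <- c("subject_id", "site_id", "visit", "form", "check_id",
                 "fields", "values", "flag_date", "message")

#' Assign flags to report time windows
#'
#' Flags are archived by age relative to a reference date: `recent` for
#' ages 0-89 days, `mid` for 90-180 days inclusive, `archive` beyond 180
#' days. The three windows partition all non-negative ages; the boundary
#' days 90 and 180 both fall in `mid`.
#'
#' @param flag_date Date vector (no later than `as_of`).
#' @param as_of Reference date.
#' @return Factor with levels `recent`, `mid`, `archive`.
#' @export
window_assign <- function(flag_date, as_of) {
  as_of <- as.Date(as_of)
  age <- as.numeric(as_of - as.Date(flag_date))
  if (any(age < 0, na.rm = TRUE)) {
    stop_crfqa("flag_date later than the as-of date (%s)", as_of)
  }
  cut(age, breaks = c(-0.5, 89.5, 180.5, Inf),
      labels = c("recent", "mid", "archive"))
}

#' Build a site-level error report
#'
#' Filters the flag table to one center x cohort stratum (e.g. MCC1-TKA),
#' one CRF domain and one time window, producing the stably sorted report
#' the data-integration team shares with sites: flagged subject IDs with
#' the violated check, implicated fields and observed values. Regenerating
#' from the same inputs yields a bit-identical report.
#'
#' @param flags Flag table from [run_checks()].
#' @param schema A [study_schema()] (maps sites to centers).
#' @param center `"MCC1"` or `"MCC2"`.
#' @param cohort Cohort label.
#' @param domain CRF domain (e.g. `"Imaging"`).
#' @param window `"recent"`, `"mid"` or `"archive"`.
#' @param as_of Reference date for window assignment.
#' @return An `error_report`: a tibble with fixed columns `subject_id`,
#'   `site_id`, `visit`, `form`, `check_id`, `fields`, `values`,
#'   `flag_date`, `message`, plus stratum metadata attributes.
#' @export
build_report <- function(flags, schema, center, cohort, domain,
                         window = c("recent", "mid", "archive"), as_of) {
  window <- match.arg(window)
  as_of <- as.Date(as_of)
  centers <- schema$sites$center[match(flags$site_id, schema$sites$site_id)]
  rows <- flags |>
    mutate(.center = centers,
           .window = window_assign(.data$flag_date, as_of)) |>
    filter(.data$.center == center, .data$cohort == !!cohort,
           .data$domain == !!domain, .data$.window == window) |>
    transmute(.data$subject_id, .data$site_id, .data$visit,
              form = .data$form_id, .data$check_id, .data$fields,
              .data$values, .data$flag_date, .data$message) |>
    arrange(.data$site_id, .data$subject_id, .data$flag_date, .data$check_id)
  structure(rows, class = c("error_report", class(rows)),
            stratum = paste(center, cohort, sep = "-"), domain = domain,
            window = window, as_of = as_of)
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> %s / %s / %s window (as of %s): %d flag(s)\n",
              attr(x, "stratum"), attr(x, "domain"), attr(x, "window"),
              format(attr(x, "as_of")), nrow(x)))
  NextMethod()
}

report_rows <- function(report) {
  as_tibble(report) |> mutate(flag_date = format(.data$flag_date))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# SpreadsheetML 2003: a plain-text XML workbook Excel/LibreOffice open
# natively; one worksheet per report, content identical to the CSV.
write_spreadsheet_xml <- function(report, path) {
  rows <- report_rows(report)
  cell <- function(v) sprintf(
    "<Cell><Data ss:Type=\"String\">%s</Data></Cell>",
    xml_escape(ifelse(is.na(v), "", as.character(v))))
  row_xml <- function(vals) paste0("<Row>", paste(purrr::map_chr(vals, cell),
                                                  collapse = ""), "</Row>")
  body <- c(
    row_xml(names(rows)),
    purrr::map_chr(seq_len(nrow(rows)), function(i) {
      row_xml(unlist(rows[i, ], use.names = FALSE))
    })
  )
  sheet_name <- xml_escape(attr(report, "domain") %||% "report")
  doc <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<Workbook xmlns=\"urn:schemas-microsoft-com:office:spreadsheet\"",
    " xmlns:ss=\"urn:schemas-microsoft-com:office:spreadsheet\">",
    sprintf("<Worksheet ss:Name=\"%s\"><Table>", sheet_name),
    body,
    "</Table></Worksheet></Workbook>"
  )
  writeLines(doc, path)
}

write_report_html <- function(report, path) {
  rows <- report_rows(report)
  td <- function(vals, tag = "td") paste0(
    "<tr>", paste0("<", tag, ">",
                   xml_escape(ifelse(is.na(vals), "", as.character(vals))),
                   "</", tag, ">", collapse = ""), "</tr>")
  doc <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    sprintf("<title>Error report %s / %s / %s</title>", attr(report, "stratum"),
            attr(report, "domain"), attr(report, "window")),
    "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 6px;font:12px sans-serif}</style>",
    "</head><body>",
    sprintf("<h1>Error report: %s &mdash; %s (%s window, as of %s)</h1>",
            xml_escape(attr(report, "stratum")), xml_escape(attr(report, "domain")),
            attr(report, "window"), format(attr(report, "as_of"))),
    "<table>",
    td(names(rows), "th"),
    purrr::map_chr(seq_len(nrow(rows)),
                   function(i) td(unlist(rows[i, ], use.names = FALSE))),
    "</table></body></html>"
  )
  writeLines(doc, path)
}

#' Export an error report
#'
#' Writes a report built by [build_report()] as `csv` (bit-stable across
#' runs), `xlsx`-compatible spreadsheet (SpreadsheetML 2003 XML, opens in
#' Excel/LibreOffice) or printable standalone `html`. All formats carry
#' exactly the same rows and columns.
#'
#' @param report An `error_report`.
#' @param path Output file path.
#' @param format `"csv"`, `"xlsx"` or `"html"`.
#' @return `path`, invisibly.
#' @export
export_report <- function(report, path, format = c("csv", "xlsx", "html")) {
  if (!format[1] %in% c("csv", "xlsx", "html")) {
    stop_crfqa("unknown export format '%s' (supported: csv, xlsx, html)",
               format[1])
  }
  format <- match.arg(format)
  switch(format,
    csv = write_csv(report_rows(report), path, na = ""),
    xlsx = write_spreadsheet_xml(report, path),
    html = write_report_html(report, path)
  )
  invisible(path)
}

#' PRO error-type breakdown by delivery instrument
#'
#' Tabulates, per PRO form and site, the percentage of each error type
#' (check kind) among that site's PRO flags, carrying the delivery
#' instrument (REDCap at MCC1 sites, MyDataHelps at MCC2 sites) so that
#' missingness can be compared across instruments. The operation only
#' tabulates; the cross-instrument comparison is the caller's reading.
#' Percentages within a (form, site) sum to 100 whenever that site has any
#' errors; sites/forms without errors are absent.
#'
#' @param flags Flag table from [run_checks()].
#' @param schema A [study_schema()].
#' @return Tibble `form_id`, `site_id`, `delivery_instrument`, `error_type`,
#'   `n`, `pct`.
#' @export
instrument_breakdown <- function(flags, schema) {
  pro_forms <- schema$forms$form_id[schema$forms$kind == "PRO"]
  pro <- flags |> filter(.data$form_id %in% pro_forms)
  if (!nrow(pro)) {
    return(tibble(form_id = character(), site_id = character(),
                  delivery_instrument = character(), error_type = character(),
                  n = integer(), pct = numeric()))
  }
  pro |>
    count(.data$form_id, .data$site_id, .data$delivery_instrument,
          error_type = .data$kind, name = "n") |>
    mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 1),
           .by = c("form_id", "site_id")) |>
    arrange(.data$form_id, .data$site_id, .data$error_type)
}

#' Per-instance PRO missingness rate by instrument
#'
#' Convenience companion to [instrument_breakdown()]: the fraction of
#' completed PRO form instances that raised a missingness flag, grouped by
#' delivery instrument. This is the quantity compared across REDCap and
#' MyDataHelps when asking whether PRO missingness depends on the survey
#' delivery instrument.
#'
#' @param flags Flag table.
#' @param statuses Output of [classify_forms()].
#' @param schema A [study_schema()].
#' @return Tibble `delivery_instrument`, `n_instances`, `n_flagged`, `rate`.
#' @export
instrument_missingness_rate <- function(flags, statuses, schema) {
  pro_forms <- schema$forms$form_id[schema$forms$kind == "PRO"]
  instances <- statuses |>
    filter(.data$form_id %in% pro_forms,
           .data$status %in% c("complete_no_error", "complete_with_error")) |>
    mutate(delivery_instrument = delivery_instrument(schema, .data$site_id,
                                                     .data$form_id))
  flagged <- flags |>
    filter(.data$form_id %in% pro_forms, .data$kind == "missingness") |>
    distinct(.data$subject_id, .data$visit, .data$form_id) |>
    mutate(flagged = TRUE)
  instances |>
    left_join(flagged, by = c("subject_id", "visit", "form_id")) |>
    summarise(n_instances = dplyr::n(),
              n_flagged = sum(!is.na(.data$flagged)),
              .by = "delivery_instrument") |>
    mutate(rate = .data$n_flagged / .data$n_instances)
}
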