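#' @importFrom rlang %||% .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Round half away from zero (REDCap-report style), as opposed to base R's
# round-half-even.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Missing sentinel: files use "", internally NA_character_.
is_blank <- function(x) is.na(x) | x == ""

# "HH:MM" -> minutes since midnight; malformed -> NA.
parse_hm <- function(x) {
  ok <- !is.na(x) & grepl("^([01][0-9]|2[0-3]):[0-5][0-9]$", x)
  out <- rep(NA_real_, length(x))
  out[ok] <- as.numeric(substr(x[ok], 1, 2)) * 60 + as.numeric(substr(x[ok], 4, 5))
  out
}

# Quiet numeric coercion; returns NA for non-numeric text.
as_num <- function(x) suppressWarnings(as.numeric(x))

# Whole calendar months from a to b (date vectors), e.g. 2024-03-13 ->
# 2025-08-13 is 17 months.
months_between <- function(a, b) {
  a <- as.POSIXlt(a)
  b <- as.POSIXlt(b)
  (b$year - a$year) * 12L + (b$mon - a$mon)
}

# First day of the calendar month.
month_floor <- function(x) lubridate::floor_date(x, "month")

stop_crfqa <- function(...) stop(sprintf(...), call. = FALSE)
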