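# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# 30-min grid spacing in seconds
GRID_SECONDS <- 1800L
STEPS_PER_DAY <- 48L
DT_HOURS <- 0.5

#' Check that timestamps form a strict regular 30-min grid.
#' @noRd
assert_grid <- function(timestamps, what = "timestamps") {
  if (length(timestamps) < 2L) return(invisible(TRUE))
  d <- diff(as.numeric(timestamps))
  if (any(d != GRID_SECONDS)) {
    bad <- which(d != GRID_SECONDS)[1L]
    stopf("%s are not a regular 30-min grid (first violation after index %d)", what, bad)
  }
  invisible(TRUE)
}

#' Build a 30-min POSIXct grid starting at local-standard midnight.
#' @noRd
make_grid <- function(start_date, n_days) {
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  t0 + seq(0L, n_days * STEPS_PER_DAY - 1L) * GRID_SECONDS
}

#' Calendar date of a grid timestamp (local standard time, no DST).
#' @noRd
grid_date <- function(timestamps) as.Date(timestamps, tz = "UTC")

#' Clock hour (fractional) of a grid timestamp.
#' @noRd
grid_hour <- function(timestamps) {
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  lt$hour + lt$min / 60
}

#' Day-of-year of a grid timestamp.
#' @noRd
grid_doy <- function(timestamps) as.POSIXlt(timestamps, tz = "UTC")$yday + 1L

#' Growing-season mask: April 1 through September 30.
#' @noRd
in_growing_season <- function(dates) {
  m <- as.POSIXlt(as.Date(dates))$mon + 1L
  m >= 4L & m <= 9L
}

#' Validate a scalar numeric config field, naming the field on failure.
#' @noRd
check_field <- function(value, field, lo = -Inf, hi = Inf, len = 1L) {
  if (length(value) != len || !is.numeric(value) || any(!is.finite(value))) {
    stopf("configuration error: field '%s' must be %d finite numeric value(s)", field, len)
  }
  if (any(value < lo) || any(value > hi)) {
    stopf("configuration error: field '%s' = %s outside [%s, %s]",
          field, format(value[1L]), format(lo), format(hi))
  }
  invisible(value)
}

#' Derive per-stage child seeds from a master seed, reproducibly.
#' @noRd
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}
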