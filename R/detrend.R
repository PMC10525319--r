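#' Fourier low-pass smoothing of a daily series
#'
#' Removes the series mean, mirror-pads the series to twice its length (which
#' makes the periodic extension continuous at both ends), takes the discrete
#' Fourier transform, zeroes every component with period shorter than
#' `cutoff_days` (hard cutoff at frequency `1/cutoff_days` per day), inverts,
#' and restores the mean. Internal gaps up to 10% of the series are linearly
#' bridged for the transform and re-masked on output.
#'
#' The filter is linear, preserves any component with period >= `cutoff_days`
#' over the interior of the series, and commutes with series reversal.
#'
#' @param x numeric daily series (regular daily grid); `NA` marks gaps.
#' @param cutoff_days cutoff period in days (>= 2 and < `length(x)`).
#' @return The smoothed series, same length, `NA` where `x` was `NA`.
#' @export
fft_lowpass <- function(x, cutoff_days) {
  n <- length(x)
  if (!is.numeric(cutoff_days) || length(cutoff_days) != 1L ||
      cutoff_days < 2 || cutoff_days >= n) {
    stopf("parameter error: cutoff_days must be in [2, series length); got %s for length %d",
          format(cutoff_days), n)
  }
  na <- is.na(x)
  if (all(na)) stopf("data-quality error: series is all missing")
  if (mean(na) > 0.10) {
    stopf("data-quality error: gap fraction %.1f%% exceeds 10%%", 100 * mean(na))
  }
  xb <- x
  if (any(na)) {
    obs <- which(!na)
    xb <- stats::approx(obs, x[obs], xout = seq_len(n), rule = 2)$y
  }
  mu <- mean(xb)
  z <- c(xb - mu, rev(xb - mu))          # mirror padding
  m <- length(z)
  k <- 0:(m - 1L)
  fcyc <- pmin(k, m - k) / m             # cycles per day on the daily grid
  ft <- stats::fft(z)
  ft[fcyc > 1 / cutoff_days] <- 0
  sm <- Re(stats::fft(ft, inverse = TRUE)) / m
  out <- sm[seq_len(n)] + mu
  out[na] <- NA_real_
  out
}

#' Detrend a daily series into smooth trend plus residuals
#'
#' @param date Date vector (regular daily grid) or `NULL` for an index grid.
#' @param x numeric daily series (um).
#' @inheritParams fft_lowpass
#' @return A `detrended_series` data frame with columns `date, original,
#'   smooth, residual, cutoff_days`; `residual = original - smooth` wherever
#'   `original` is present.
#' @export
residualize <- function(x, cutoff_days, date = NULL) {
  if (is.null(date)) {
    date <- as.Date("2000-01-01") + seq_along(x) - 1L
  }
  if (length(date) != length(x)) stopf("date and x lengths differ")
  if (length(x) > 1L && any(diff(as.integer(as.Date(date))) != 1L)) {
    stopf("residualize requires a regular daily grid")
  }
  sm <- fft_lowpass(x, cutoff_days)
  out <- data.frame(date = as.Date(date), original = x, smooth = sm,
                    residual = x - sm, cutoff_days = cutoff_days)
  class(out) <- c("detrended_series", "data.frame")
  out
}

#' @export
print.detrended_series <- function(x, ...) {
  cat(sprintf("<detrended_series> %d days, cutoff %g days, residual SD %.3g um\n",
              nrow(x), x$cutoff_days[1L], stats::sd(x$residual, na.rm = TRUE)))
  invisible(x)
}
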