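#' Daily statistics of a radius trace
#'
#' Reduces a corrected 30-min trace to per-calendar-day metrics (local
#' standard time): mean, maximum, minimum, amplitude (max - min), the clock
#' hour of the extrema (earliest record attaining each extremum) and the
#' record count. Days whose coverage falls below `min_coverage` of the 48
#' possible records keep their `n_records` but have all metrics set to `NA`.
#'
#' @param trace a [sensor_trace()] (thermally corrected).
#' @param min_coverage minimum fraction of the 48 records required for a
#'   valid day (default 0.9).
#' @return A data frame `date, tree_id, position, daily_mean, daily_max,
#'   daily_min, amplitude, time_of_max, time_of_min, n_records`.
#' @export
daily_radius_stats <- function(trace, min_coverage = 0.9) {
  if (!inherits(trace, "sensor_trace")) stopf("trace must be a sensor_trace")
  dts <- grid_date(trace$timestamp)
  hrs <- grid_hour(trace$timestamp)
  days <- sort(unique(dts))
  need <- ceiling(min_coverage * STEPS_PER_DAY)
  rows <- lapply(days, function(d) {
    sel <- dts == d & !is.na(trace$radius)
    v <- trace$radius[sel]
    h <- hrs[sel]
    n <- length(v)
    if (n < need) {
      return(data.frame(date = d, daily_mean = NA_real_, daily_max = NA_real_,
                        daily_min = NA_real_, amplitude = NA_real_,
                        time_of_max = NA_real_, time_of_min = NA_real_,
                        n_records = n))
    }
    mx <- max(v); mn <- min(v)
    data.frame(date = d, daily_mean = mean(v), daily_max = mx, daily_min = mn,
               amplitude = mx - mn,
               time_of_max = h[which(v == mx)[1L]],
               time_of_min = h[which(v == mn)[1L]],
               n_records = n)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(date = out$date, tree_id = attr(trace, "tree_id"),
                    position = attr(trace, "position"),
                    out[, setdiff(names(out), "date")])
  out
}

#' Daily mean change ("daily mean approach")
#'
#' The radius change assigned to day d is `mean(day d) - mean(day d-1)`;
#' it is `NA` when either day is invalid or the days are not consecutive.
#' Over a gapless span the changes telescope to (last mean - first mean).
#'
#' @param daily either a [sensor_trace()] or a table from
#'   [daily_radius_stats()].
#' @param min_coverage passed to [daily_radius_stats()] when `daily` is a
#'   trace.
#' @return A data frame `date, daily_mean_change`.
#' @export
daily_mean_change <- function(daily, min_coverage = 0.9) {
  if (inherits(daily, "sensor_trace")) {
    daily <- daily_radius_stats(daily, min_coverage)
  }
  if (sum(!is.na(daily$daily_mean)) < 2L) {
    stopf("daily_mean_change needs at least 2 valid days")
  }
  d <- daily[order(daily$date), ]
  prev_mean <- c(NA_real_, d$daily_mean[-nrow(d)])
  prev_date <- c(as.Date(NA), d$date[-nrow(d)])
  consec <- !is.na(prev_date) & as.integer(d$date - prev_date) == 1L
  chg <- ifelse(consec, d$daily_mean - prev_mean, NA_real_)
  data.frame(date = d$date, daily_mean_change = chg)
}

#' Daily climate aggregates
#'
#' Per calendar day: max/mean/min of air temperature, VPD and RH; mean solar
#' radiation; mean soil water content; precipitation sum.
#'
#' @param climate a [climate_trace()].
#' @return A data frame with columns `date, t_max, t_mean, t_min, vpd_max,
#'   vpd_mean, vpd_min, rh_max, rh_mean, rh_min, sr_mean, swc_mean, p_sum`.
#' @export
daily_climate <- function(climate) {
  if (!inherits(climate, "climate_trace")) stopf("climate must be a climate_trace")
  dts <- grid_date(climate$timestamp)
  agg <- function(v, f) as.numeric(tapply(v, dts, f, na.rm = TRUE))
  days <- as.Date(names(tapply(climate$t_air, dts, length)))
  out <- data.frame(
    date = days,
    t_max = agg(climate$t_air, max), t_mean = agg(climate$t_air, mean),
    t_min = agg(climate$t_air, min),
    vpd_max = agg(climate$vpd, max), vpd_mean = agg(climate$vpd, mean),
    vpd_min = agg(climate$vpd, min),
    rh_max = agg(climate$rh, max), rh_mean = agg(climate$rh, mean),
    rh_min = agg(climate$rh, min),
    sr_mean = agg(climate$sr, mean), swc_mean = agg(climate$swc, mean),
    p_sum = agg(climate$p, sum))
  out[order(out$date), , drop = FALSE]
}

#' Growing-season climate summary
#'
#' Aggregates daily climate over each year's growing season (April 1 through
#' September 30): seasonal means with seasonal maxima in companion columns,
#' and the precipitation total with the maximum daily sum.
#'
#' @param daily a [daily_climate()] table.
#' @return A data frame `year, t_mean, t_max, vpd_mean, vpd_max, p_total,
#'   p_daily_max, swc_mean, swc_max`, one row per year.
#' @export
growing_season_summary <- function(daily) {
  sel <- daily[in_growing_season(daily$date), , drop = FALSE]
  if (!nrow(sel)) stopf("validation error: no growing-season days in input")
  yr <- as.POSIXlt(sel$date)$year + 1900L
  rows <- lapply(split(sel, yr), function(g) {
    data.frame(year = as.POSIXlt(g$date)$year[1L] + 1900L,
               t_mean = mean(g$t_mean, na.rm = TRUE),
               t_max = max(g$t_max, na.rm = TRUE),
               vpd_mean = mean(g$vpd_mean, na.rm = TRUE),
               vpd_max = max(g$vpd_max, na.rm = TRUE),
               p_total = sum(g$p_sum, na.rm = TRUE),
               p_daily_max = max(g$p_sum, na.rm = TRUE),
               swc_mean = mean(g$swc_mean, na.rm = TRUE),
               swc_max = max(g$swc_mean, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
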