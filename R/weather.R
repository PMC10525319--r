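#' Configuration for the synthetic weather generator
#'
#' Defaults describe a dry inner-Alpine growing season: mean air temperature
#' around 15 deg C April-September with a ~12 deg C diurnal range, relative
#' humidity strongly anticorrelated with temperature (afternoon RH down to
#' ~20% on hot clear days, so VPD can reach 4-6 kPa), peak clear-sky solar
#' radiation ~900 W m-2, about 2.4 mm precipitation per day on average, and
#' shallow coarse soil whose water content swings between ~5 and ~34 vol %.
#'
#' @param start_date first day (ISO date string or Date); the grid starts at
#'   local-standard midnight.
#' @param n_days number of simulated days (48 half-hour records each).
#' @param t_seasonal_mean,t_seasonal_amplitude annual mean and half-range of
#'   the seasonal air-temperature cycle (deg C), peaking in mid-July.
#' @param t_diurnal_amplitude peak-to-trough diurnal temperature range (deg C),
#'   warmest around 15:00.
#' @param rh_base,rh_t_slope relative-humidity baseline (%) and decline per
#'   deg C of diurnal/synoptic warming; RH is clipped to `[5, 100]`.
#' @param sr_peak clear-sky solar radiation maximum (W m-2).
#' @param cloud_fraction probability that a day is overcast.
#' @param rain_event_rate mean number of rain events per day (Poisson).
#' @param rain_event_mean mean rainfall per event (mm, exponential).
#' @param swc_max,swc_min soil water content bounds (vol %).
#' @param swc_drain_rate base fractional drainage of plant-available soil
#'   water per day; actual loss increases with daily mean VPD.
#' @param seed integer RNG seed; identical configs give identical output.
#' @return A `weather_config` list.
#' @export
weather_config <- function(start_date = "2019-04-01", n_days = 183L,
                           t_seasonal_mean = 14, t_seasonal_amplitude = 9,
                           t_diurnal_amplitude = 12,
                           rh_base = 65, rh_t_slope = 5,
                           sr_peak = 900,
                           cloud_fraction = 0.3,
                           rain_event_rate = 0.3, rain_event_mean = 8,
                           swc_max = 33.5, swc_min = 5.4,
                           swc_drain_rate = 0.05,
                           seed = 1L) {
  cfg <- list(start_date = as.character(start_date), n_days = as.integer(n_days),
              t_seasonal_mean = t_seasonal_mean,
              t_seasonal_amplitude = t_seasonal_amplitude,
              t_diurnal_amplitude = t_diurnal_amplitude,
              rh_base = rh_base, rh_t_slope = rh_t_slope, sr_peak = sr_peak,
              cloud_fraction = cloud_fraction,
              rain_event_rate = rain_event_rate,
              rain_event_mean = rain_event_mean,
              swc_max = swc_max, swc_min = swc_min,
              swc_drain_rate = swc_drain_rate, seed = as.integer(seed))
  validate_weather_config(cfg)
  class(cfg) <- "weather_config"
  cfg
}

validate_weather_config <- function(cfg) {
  if (is.na(cfg$n_days) || cfg$n_days < 1L) {
    stopf("configuration error: field 'n_days' must be >= 1")
  }
  check_field(cfg$t_seasonal_mean, "t_seasonal_mean", -40, 50)
  check_field(cfg$t_seasonal_amplitude, "t_seasonal_amplitude", 0, 40)
  check_field(cfg$t_diurnal_amplitude, "t_diurnal_amplitude", 0, 40)
  check_field(cfg$rh_base, "rh_base", 0, 100)
  check_field(cfg$rh_t_slope, "rh_t_slope", 0, 20)
  check_field(cfg$sr_peak, "sr_peak", 0, 1500)
  check_field(cfg$cloud_fraction, "cloud_fraction", 0, 1)
  check_field(cfg$rain_event_rate, "rain_event_rate", 0, 50)
  check_field(cfg$rain_event_mean, "rain_event_mean", 0, 500)
  check_field(cfg$swc_min, "swc_min", 0, 100)
  check_field(cfg$swc_max, "swc_max", cfg$swc_min, 100)
  check_field(cfg$swc_drain_rate, "swc_drain_rate", 0, 5)
  invisible(cfg)
}

#' Generate a synthetic 30-min microclimate record
#'
#' Produces a [climate_trace()] on a regular 30-min grid from a stochastic
#' weather model: a seasonal + diurnal + AR(1)-synoptic air-temperature
#' signal; daylight-shaped solar radiation with seasonally varying day
#' length, damped on overcast days; relative humidity anticorrelated with
#' temperature and saturating during rain; Poisson rain events; and a
#' single-bucket soil-moisture model that fills with rain and drains
#' exponentially, faster on high-VPD days. SR is exactly zero at night,
#' RH stays in `[5, 100]`, SWC stays in `[swc_min, swc_max]`, and the same
#' config (including seed) always reproduces the same series.
#'
#' @param config a [weather_config()].
#' @return A [climate_trace()] of `n_days * 48` records.
#' @export
generate_weather <- function(config) {
  if (!inherits(config, "weather_config")) config <- do.call(weather_config, config)
  validate_weather_config(config)
  withr::with_seed(config$seed, generate_weather_impl(config))
}

generate_weather_impl <- function(cfg) {
  ts <- make_grid(cfg$start_date, cfg$n_days)
  n <- length(ts)
  doy <- grid_doy(ts)
  hour <- grid_hour(ts)
  day_idx <- rep(seq_len(cfg$n_days), each = STEPS_PER_DAY)
  nd <- cfg$n_days

  # --- daily-scale stochastic drivers ---------------------------------------
  # AR(1) synoptic temperature anomaly (sd ~2.5 C, persistence 0.7)
  syn <- numeric(nd)
  innov <- stats::rnorm(nd, 0, 2.5 * sqrt(1 - 0.7^2))
  syn[1L] <- stats::rnorm(1L, 0, 2.5)
  if (nd > 1L) for (d in 2:nd) syn[d] <- 0.7 * syn[d - 1L] + innov[d]

  # rain events: Poisson count per day, exponential amounts
  n_events <- stats::rpois(nd, cfg$rain_event_rate)
  cloudy <- stats::runif(nd) < cfg$cloud_fraction | n_events > 0L
  clearness <- ifelse(cloudy, stats::runif(nd, 0.15, 0.55),
                      stats::runif(nd, 0.85, 1.0))

  p <- numeric(n)
  for (d in which(n_events > 0L)) {
    for (e in seq_len(n_events[d])) {
      amount <- stats::rexp(1L, 1 / cfg$rain_event_mean)
      nslot <- sample(1:4, 1L)
      start <- sample(seq_len(STEPS_PER_DAY - nslot + 1L), 1L)
      idx <- (d - 1L) * STEPS_PER_DAY + start + seq_len(nslot) - 1L
      p[idx] <- p[idx] + amount / nslot
    }
  }

  # --- air temperature ------------------------------------------------------
  t_seas <- cfg$t_seasonal_mean +
    cfg$t_seasonal_amplitude * cos(2 * pi * (doy - 196) / 365.25)
  diurnal_damp <- ifelse(cloudy[day_idx], 0.5, 1.0)
  t_air <- t_seas + syn[day_idx] - 2 * cloudy[day_idx] +
    diurnal_damp * (cfg$t_diurnal_amplitude / 2) * cos(2 * pi * (hour - 15) / 24)

  # --- solar radiation: daylight half-sine, seasonal day length -------------
  daylength <- 12 + 4 * cos(2 * pi * (doy - 172) / 365.25)
  sunrise <- 12 - daylength / 2
  seas_sr <- 0.6 + 0.4 * cos(2 * pi * (doy - 172) / 365.25)
  shape <- sin(pi * (hour - sunrise) / daylength)
  shape[hour <= sunrise | hour >= sunrise + daylength] <- 0
  shape[shape < 0] <- 0
  sr <- cfg$sr_peak * seas_sr * clearness[day_idx] * shape

  # --- relative humidity ----------------------------------------------------
  rh <- cfg$rh_base - cfg$rh_t_slope * (t_air - t_seas) + stats::rnorm(n, 0, 3)
  rh[p > 0] <- pmax(rh[p > 0], 96)
  rh <- pmin(pmax(rh, 5), 100)

  vpd <- compute_vpd(t_air, rh, ts)

  # --- soil water bucket ----------------------------------------------------
  vpd_day <- tapply(vpd, day_idx, mean)
  infil <- 0.3                                   # vol % gained per mm of rain
  drain_step <- cfg$swc_drain_rate / STEPS_PER_DAY
  swc <- numeric(n)
  s <- 0.6 * cfg$swc_max + 0.4 * cfg$swc_min     # start moderately wet
  for (i in seq_len(n)) {
    d <- day_idx[i]
    s <- s + infil * p[i]
    s <- s - drain_step * (s - cfg$swc_min) * (1 + 0.5 * vpd_day[[d]])
    s <- min(max(s, cfg$swc_min), cfg$swc_max)
    swc[i] <- s
  }

  climate_trace(ts, t_air = t_air, rh = rh, sr = sr, p = p, swc = swc, vpd = vpd)
}
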