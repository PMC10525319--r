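# Shared fixture builders: everything is generated in code at test time.

# Hydraulic parameters without observation artifacts (noise, thermal, gaps).
quiet_params <- function(...) {
  args <- list(...)
  defaults <- list(noise_sd = 0, gap_fraction = 0, alpha_x = 0, alpha_b = 0)
  do.call(hydraulic_params, utils::modifyList(defaults, args))
}

small_climate <- function(n_days = 30, seed = 1, ...) {
  generate_weather(weather_config(n_days = n_days, seed = seed, ...))
}

# A constant-conditions climate trace (saturated air unless stated).
flat_climate <- function(n_days = 5, t_air = 15, rh = 100, swc = 20) {
  ts <- seq(as.POSIXct("2019-06-01", tz = "UTC"), by = 1800,
            length.out = n_days * 48)
  climate_trace(ts, t_air = rep(t_air, length(ts)), rh = rep(rh, length(ts)),
                sr = rep(0, length(ts)), p = rep(0, length(ts)),
                swc = rep(swc, length(ts)))
}

make_trace <- function(vals, position = "xylem", tree = "t1",
                       start = "2019-06-01", corrected = TRUE) {
  ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"), by = 1800,
            length.out = length(vals))
  sensor_trace(ts, vals, tree_id = tree, position = position,
               corrected = corrected)
}

mark_corrected <- function(tr) {
  attr(tr, "corrected") <- TRUE
  tr
}

# Daily climate table with prescribed columns, for correlation-table tests.
fake_daily_climate <- function(n, seed = 1, start = "2019-04-01") {
  withr::with_seed(seed, {
    data.frame(date = as.Date(start) + seq_len(n) - 1L,
               t_max = rnorm(n, 25, 5), t_mean = rnorm(n, 17, 4),
               t_min = rnorm(n, 9, 3),
               vpd_max = rexp(n, 1 / 2) + 0.1, vpd_mean = rexp(n, 2) + 0.05,
               vpd_min = rexp(n, 10),
               rh_max = runif(n, 80, 100), rh_mean = runif(n, 50, 90),
               rh_min = runif(n, 15, 60),
               sr_mean = runif(n, 50, 350), swc_mean = runif(n, 6, 30),
               p_sum = rexp(n, 1 / 2) * rbinom(n, 1, 0.4))
  })
}
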