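test_that("saturated air with no growth or artifacts yields constant radii", {
  cl <- flat_climate(n_days = 4, rh = 100)
  sim <- simulate_stem(cl, quiet_params(growth_total = 0, seed = 1))
  expect_lt(diff(range(sim$xylem$radius)), 1e-9)
  expect_lt(diff(range(sim$overbark$radius)), 1e-9)
  expect_true(all(sim$truth$states$E == 0))
})

test_that("storage water balance closes for any seed", {
  cl <- small_climate(n_days = 20, seed = 2)
  for (seed in 1:3) {
    sim <- simulate_stem(cl, hydraulic_params(seed = seed))
    st <- sim$truth$states
    turnover <- sum(abs(st$q)) * 0.5
    drift <- abs(st$W[nrow(st)] - 0 + sum(st$q) * 0.5)
    expect_lt(drift, 1e-6 * turnover)
  }
})

test_that("without transpiration the stem relaxes to soil water potential", {
  cl <- flat_climate(n_days = 8, rh = 100, swc = 20)
  sim <- simulate_stem(cl, quiet_params(growth_total = 0, seed = 1))
  st <- sim$truth$states
  psi_soil <- st$psi_soil[1L]
  last_day <- st[st$timestamp >= max(st$timestamp) - 86400, ]
  expect_lt(max(abs(last_day$psi_x - psi_soil)), 1e-6)
  expect_lt(max(abs(last_day$psi_s - psi_soil)), 1e-6)
})

test_that("bark amplitude exceeds xylem amplitude whenever bark is more elastic", {
  cl <- small_climate(n_days = 15, seed = 4)
  for (ratio in c(2, 10)) {
    sim <- simulate_stem(cl, quiet_params(growth_total = 0, eps_b = ratio * 30,
                                          seed = 1))
    st <- sim$truth$states
    d <- as.Date(st$timestamp)
    amp_x <- tapply(st$r_x_true, d, function(v) diff(range(v)))
    amp_b <- tapply(st$b_true, d, function(v) diff(range(v)))
    expect_true(all(amp_b > amp_x))
  }
})

test_that("the bark-behind-xylem lag increases with the storage time constant", {
  cl <- small_climate(n_days = 20, seed = 6)
  lag_for_tau <- function(r_stor) {
    sim <- simulate_stem(cl, quiet_params(growth_total = 0, r_stor = r_stor,
                                          c_stor = 0.5, seed = 1))
    ib <- decompose_inner_bark(mark_corrected(sim$overbark),
                               mark_corrected(sim$xylem))
    estimate_lag(sim$xylem$radius, ib$radius, sim$xylem$timestamp)
  }
  lags <- vapply(c(2, 4, 8), lag_for_tau, numeric(1))  # tau = 1, 2, 4 h
  expect_true(all(diff(lags) > 0))
  expect_gt(lags[1], 0)
})

test_that("the xylem minimum trails peak transpiration by at most the storage pull", {
  # the quasi-steady xylem node tracks E, but the 0.667 weight on the lagged
  # storage potential (tau = 2 h) lets the minimum trail the E peak; on
  # strongly forced days it must never precede it and trails by a few hours
  cl <- small_climate(n_days = 60, seed = 8)
  sim <- simulate_stem(cl, quiet_params(seed = 1))
  st <- sim$truth$states
  d <- as.Date(st$timestamp)
  lt <- as.POSIXlt(st$timestamp, tz = "UTC")
  hr <- lt$hour + lt$min / 60
  offsets <- vapply(split(seq_len(nrow(st)), d), function(i) {
    if (max(st$E[i]) < 0.3 * max(st$E)) return(NA_real_)
    hr[i][which.min(st$r_x_true[i])] - hr[i][which.max(st$E[i])]
  }, numeric(1))
  offsets <- offsets[!is.na(offsets)]
  expect_gt(length(offsets), 20)
  expect_true(all(offsets >= -0.5))
  expect_true(all(offsets <= 6))
  expect_lte(median(offsets), 2)  # of the order of tau
})

test_that("identical seed reproduces measurements including gap placement", {
  cl <- small_climate(n_days = 10, seed = 3)
  p <- hydraulic_params(gap_fraction = 0.1, seed = 21)
  s1 <- simulate_stem(cl, p)
  s2 <- simulate_stem(cl, p)
  expect_identical(s1$xylem$radius, s2$xylem$radius)
  expect_identical(is.na(s1$overbark$radius), is.na(s2$overbark$radius))
  expect_gt(sum(is.na(s1$xylem$radius)), 0)
})

test_that("climate gaps and numerical instability raise informative errors", {
  cl <- small_climate(n_days = 10, seed = 3)
  cl_gap <- cl
  cl_gap$t_air[100] <- NA
  expect_error(simulate_stem(cl_gap, hydraulic_params()), "gap")
  expect_error(
    simulate_stem(cl, hydraulic_params(g_max = 100, seed = 1)),
    "30-min step")
})

test_that("a stand shares forcing but differs in observation noise", {
  cl <- small_climate(n_days = 6, seed = 9)
  stand <- simulate_stand(cl, hydraulic_params(seed = 5), n_trees = 3)
  expect_length(stand, 3)
  expect_false(identical(stand$tree1$xylem$radius, stand$tree2$xylem$radius))
  expect_identical(stand$tree1$truth$states$E, stand$tree2$truth$states$E)
})
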