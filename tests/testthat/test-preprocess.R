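test_that("VPD is zero in saturated air and matches the Magnus value at 25 C / 50 %", {
  t_grid <- seq(-10, 40, by = 5)
  expect_equal(compute_vpd(t_grid, rep(100, length(t_grid))),
               rep(0, length(t_grid)))
  expect_equal(compute_vpd(25, 50), 1.584, tolerance = 0.01 / 1.584)
})

test_that("VPD increases with temperature and decreases with humidity", {
  t_grid <- seq(0, 40, by = 0.5)
  for (rh in c(20, 50, 80)) {
    expect_true(all(diff(compute_vpd(t_grid, rep(rh, length(t_grid)))) > 0))
  }
  rh_grid <- seq(0, 100, by = 1)
  for (tt in c(5, 20, 35)) {
    expect_true(all(diff(compute_vpd(rep(tt, length(rh_grid)), rh_grid)) < 0))
  }
})

test_that("VPD validation names the offending records", {
  ts <- seq(as.POSIXct("2019-06-01", tz = "UTC"), by = 1800, length.out = 4)
  expect_error(compute_vpd(c(10, 10, 10, 10), c(50, 120, 50, -3), ts),
               "RH outside \\[0, 100\\] at 2 record")
  expect_error(compute_vpd(-45, 50), "-40")
})

test_that("thermal correction is the identity at constant temperature", {
  tr <- make_trace(sin(1:96), corrected = FALSE)
  out <- thermal_correct(tr, rep(12, 96))
  expect_equal(out$radius, tr$radius)
  expect_true(attr(out, "corrected"))
})

test_that("a 10-degree warming on a constant xylem trace removes 10.8 um", {
  tr <- make_trace(rep(100, 96), corrected = FALSE)
  t_air <- seq(0, 10, length.out = 96)
  out <- thermal_correct(tr, t_air,
                         preprocess_config(reference_temperature = 0))
  expect_equal(out$radius[96], 89.2)
  # over-bark sensors use the smaller sensor-only coefficient
  ob <- make_trace(rep(100, 96), position = "overbark", corrected = FALSE)
  out_ob <- thermal_correct(ob, t_air,
                            preprocess_config(reference_temperature = 0))
  expect_equal(out_ob$radius[96], 98)
})

test_that("correction with the true coefficient decouples the trace from temperature", {
  cl <- small_climate(n_days = 25, seed = 11)
  sim <- simulate_stem(cl, hydraulic_params(noise_sd = 0.5, gap_fraction = 0,
                                            alpha_x = 1.08, alpha_b = 0.2,
                                            seed = 2))
  xy <- thermal_correct(sim$xylem, cl)
  resid <- xy$radius - sim$truth$states$r_x_true
  expect_lt(abs(cor(resid, cl$t_air)), 0.05)
})

test_that("double correction and misaligned temperature are rejected", {
  tr <- make_trace(rep(1, 96), corrected = FALSE)
  once <- thermal_correct(tr, rep(10, 96))
  expect_error(thermal_correct(once, rep(10, 96)), "already")
  expect_error(thermal_correct(tr, rep(10, 50)), "alignment")
  cl <- small_climate(n_days = 1, seed = 1)  # grid does not cover the trace
  tr2 <- make_trace(rep(1, 96), start = "2025-01-01", corrected = FALSE)
  expect_error(thermal_correct(tr2, cl), "alignment")
})

test_that("inner-bark decomposition subtracts xylem from over-bark", {
  ob <- make_trace(c(120, 118, 121), position = "overbark")
  xy <- make_trace(c(20, 19, 20), position = "xylem")
  ib <- decompose_inner_bark(ob, xy)
  expect_equal(ib$radius, c(100, 99, 101))
  expect_identical(attr(ib, "position"), "innerbark")
  # identical inputs give an identically zero inner bark
  expect_true(all(decompose_inner_bark(ob, make_trace(c(120, 118, 121),
                                                      position = "xylem"))$radius == 0))
})

test_that("decomposition propagates gaps and reconstructs the over-bark record", {
  ob <- make_trace(c(10, NA, 12, 13, 14, 15), position = "overbark")
  xy <- make_trace(c(1, 2, NA, 3, 4, 5), position = "xylem")
  ib <- decompose_inner_bark(ob, xy)
  expect_true(all(is.na(ib$radius[2:3])))
  both <- !is.na(ib$radius)
  expect_equal(ib$radius[both] + xy$radius[both], ob$radius[both])
})

test_that("decomposition enforces identity, correction state and alignment", {
  ob <- make_trace(1:5, position = "overbark", tree = "a")
  xy_other <- make_trace(1:5, position = "xylem", tree = "b")
  expect_error(decompose_inner_bark(ob, xy_other), "identity")
  xy_raw <- make_trace(1:5, position = "xylem", tree = "a", corrected = FALSE)
  expect_error(decompose_inner_bark(ob, xy_raw), "corrected")
})

test_that("noiseless simulation recovers the true inner-bark thickness", {
  cl <- small_climate(n_days = 20, seed = 12)
  sim <- simulate_stem(cl, quiet_params(seed = 3))
  ib <- decompose_inner_bark(mark_corrected(sim$overbark),
                             mark_corrected(sim$xylem))
  dev <- ib$radius - sim$truth$states$b_true
  expect_lt(max(abs(dev - dev[1])), 1e-6)
})

test_that("correct-then-decompose equals decomposing individually corrected traces", {
  cl <- small_climate(n_days = 10, seed = 13)
  sim <- simulate_stem(cl, hydraulic_params(noise_sd = 0.5, gap_fraction = 0,
                                            alpha_x = 1.08, alpha_b = 0.2,
                                            seed = 4))
  ib1 <- decompose_inner_bark(thermal_correct(sim$overbark, cl),
                              thermal_correct(sim$xylem, cl))
  # manual route: subtract each sensor's own expansion before differencing
  dT <- cl$t_air - cl$t_air[1L]
  manual <- (sim$overbark$radius - 0.2 * dT) - (sim$xylem$radius - 1.08 * dT)
  expect_equal(ib1$radius, manual)
})

test_that("tree aggregation averages and reports the standard error", {
  a <- make_trace(c(0, 2), position = "xylem", tree = "a")
  b <- make_trace(c(2, 4), position = "xylem", tree = "b")
  agg <- aggregate_trees(list(a, b), rezero = FALSE)
  expect_equal(agg$mean, c(1, 3))
  expect_equal(agg$se, c(1, 1))
  # identical traces have zero spread
  agg2 <- aggregate_trees(list(a, make_trace(c(0, 2), tree = "c")))
  expect_equal(agg2$se, c(0, 0))
  expect_error(aggregate_trees(list()), "empty")
  expect_error(aggregate_trees(list(a, make_trace(c(1, 2), position = "overbark"))),
               "position")
})

test_that("the stand mean is closer to the noiseless truth than single trees", {
  cl <- small_climate(n_days = 8, seed = 14)
  wins <- 0L
  reps <- 100L
  for (r in seq_len(reps)) {
    stand <- simulate_stand(cl, hydraulic_params(noise_sd = 1, gap_fraction = 0,
                                                 alpha_x = 0, alpha_b = 0,
                                                 seed = 1000 + r), n_trees = 4)
    truth <- stand$tree1$truth$states
    truth_ob <- truth$r_x_true + truth$b_true
    agg <- aggregate_trees(lapply(stand, `[[`, "overbark"), rezero = FALSE)
    rmse <- function(v) sqrt(mean((v - truth_ob)^2))
    single <- vapply(stand, function(s) rmse(s$overbark$radius), numeric(1))
    if (rmse(agg$mean) < min(single)) wins <- wins + 1L
  }
  expect_gte(wins / reps, 0.95)
})
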