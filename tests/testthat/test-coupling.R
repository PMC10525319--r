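test_that("spearman correlation handles monotone, antitone and tied data", {
  s <- spearman_cor(1:5, (1:5)^2)
  expect_equal(s$rho, 1)
  expect_equal(spearman_cor(1:5, 5:1)$rho, -1)
  x <- c(1, 2, 2, 3, 3)
  y <- c(1, 3, 2, 4, 4)
  expect_equal(spearman_cor(x, y)$rho, brute_spearman(x, y), tolerance = 1e-12)
})

test_that("spearman matches the brute-force average-rank oracle on random ties", {
  withr::with_seed(10, {
    for (i in 1:200) {
      n <- sample(5:20, 1)
      x <- sample(1:6, n, replace = TRUE) + rnorm(n, 0, 0.01 * rbinom(1, 1, 0.5))
      y <- sample(1:6, n, replace = TRUE)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) next
      expect_equal(spearman_cor(x, y)$rho, brute_spearman(x, y), tolerance = 1e-12)
    }
  })
})

test_that("spearman is invariant under strictly monotone transforms", {
  withr::with_seed(11, {
    x <- rnorm(40)
    y <- x + rnorm(40)
  })
  base <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(exp(x), y)$rho, base)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$rho, base)
})

test_that("spearman rejects constant input and tiny samples, and drops NA pairs", {
  expect_error(spearman_cor(rep(1, 10), rnorm(10)), "tied")
  expect_error(spearman_cor(1:4, 1:4), ">= 5")
  s <- spearman_cor(c(1:6, NA), c(2:7, 3))
  expect_equal(s$n, 6L)
})

test_that("the correlation table agrees with spearman and flags significance", {
  clim <- fake_daily_climate(120, seed = 12)
  rad <- data.frame(date = clim$date, tree_id = "m", position = "xylem",
                    daily_mean = -clim$t_mean + rnorm(120, 0, 2),
                    daily_max = clim$t_max,   # response equals a predictor
                    daily_min = rnorm(120),
                    amplitude = abs(rnorm(120)), time_of_max = 6,
                    time_of_min = 15, n_records = 48L)
  tab <- correlation_table(rad, clim)
  cell <- tab[tab$response == "Xyl_max" & tab$predictor == "t_max", ]
  expect_equal(cell$rho, 1)
  expect_equal(cell$stars, "***")
  cell2 <- tab[tab$response == "Xyl_mean" & tab$predictor == "t_mean", ]
  ref <- spearman_cor(rad$daily_mean, clim$t_mean)
  expect_equal(cell2$rho, ref$rho)
  expect_equal(cell2$p, ref$p)
  # winter-only data leave an empty seasonal mask
  winter <- clim[1:60, ]
  winter$date <- as.Date("2019-01-01") + 0:59
  rad_w <- rad[1:60, ]
  rad_w$date <- winter$date
  expect_error(correlation_table(rad_w, winter), "seasonal mask")
})

test_that("a permuted response shows no spurious correlation at n = 500", {
  clim <- fake_daily_climate(500, seed = 13)
  withr::with_seed(14, {
    ok <- 0L
    for (r in 1:20) {
      rad <- data.frame(date = clim$date, tree_id = "m", position = "xylem",
                        daily_mean = sample(clim$t_mean),
                        daily_max = sample(clim$t_max),
                        daily_min = sample(clim$swc_mean),
                        amplitude = 1, time_of_max = 6, time_of_min = 15,
                        n_records = 48L)
      tab <- correlation_table(rad, clim, season_only = FALSE)
      if (all(abs(tab$rho) < 0.2)) ok <- ok + 1L
    }
  })
  expect_gte(ok, 19L)
})

test_that("stepwise regression recovers a known generative model", {
  withr::with_seed(15, {
    x1 <- rnorm(200)
    x2 <- rnorm(200)
    y <- 2 * x1 + rnorm(200, 0, 0.1)
  })
  m <- stepwise_regression(y, data.frame(x1 = x1, x2 = x2))
  expect_identical(m$selected, "x1")
  est <- m$coefficients$estimate[m$coefficients$term == "x1"]
  expect_lt(abs(est - 2) / 2, 0.05)
  expect_gt(m$adj_r_squared, 0.99)
})

test_that("an empty pool yields the intercept-only model", {
  m <- stepwise_regression(rnorm(30), data.frame(row.names = 1:30))
  expect_length(m$selected, 0)
  expect_equal(m$adj_r_squared, 0)
})

test_that("stepwise selection matches the RSS-based oracle and ignores input order", {
  withr::with_seed(16, {
    for (r in 1:10) {
      n <- 120
      k <- sample(3:5, 1)
      X <- as.data.frame(matrix(rnorm(n * k), n, k))
      names(X) <- paste0("v", seq_len(k))
      beta <- ifelse(runif(k) < 0.5, 0, runif(k, 0.2, 1))
      y <- as.matrix(X) %*% beta + rnorm(n)
      m <- stepwise_regression(y, X)
      expect_identical(sort(m$selected), oracle_stepwise(y, X))
      m2 <- stepwise_regression(y, X[rev(names(X))])
      expect_identical(sort(m2$selected), sort(m$selected))
    }
  })
})

test_that("perfectly collinear predictors are rejected with their names", {
  withr::with_seed(17, x <- rnorm(60))
  X <- data.frame(a = x, b = 2 * x, c = rnorm(60))
  expect_error(stepwise_regression(rnorm(60), X), "'a' and 'b'")
})

test_that("the logarithmic amplitude fit recovers exact and null relationships", {
  withr::with_seed(18, v <- runif(80, 0.2, 5))
  amp <- 2 + 3 * log(v)
  # an exact model triggers lm's perfect-fit warning; that is the point here
  f <- suppressWarnings(fit_log_amplitude(amp, v))
  expect_equal(f$a, 2, tolerance = 1e-8)
  expect_equal(f$b, 3, tolerance = 1e-8)
  expect_equal(f$r_squared, 1)
  withr::with_seed(19, amp0 <- rnorm(80, 10, 1))
  f0 <- fit_log_amplitude(amp0, v)
  expect_lt(abs(f0$b), 2 * f0$se_b)
  expect_lt(f0$r_squared, 0.05)
})

test_that("the log fit excludes near-zero VPD days and checks data quantity", {
  v <- c(rep(0.01, 30), runif(20, 0.5, 3))
  amp <- seq_along(v)
  f <- fit_log_amplitude(amp, v)
  expect_equal(f$n, 20L)
  expect_error(fit_log_amplitude(amp[1:35], v[1:35]), "data-quantity")
})

test_that("lag estimation recovers constructed shifts with interpolation", {
  ts <- seq(as.POSIXct("2019-06-01", tz = "UTC"), by = 1800, length.out = 6 * 48)
  h <- as.numeric(ts - ts[1], units = "hours")
  base <- sin(2 * pi * h / 24) + 0.3 * sin(2 * pi * h / 8)
  expect_equal(estimate_lag(base, base, ts), 0)
  shifted <- c(rep(base[1], 4), base[seq_len(length(base) - 4)])
  expect_equal(estimate_lag(base, shifted, ts), 2, tolerance = 0.26)
  expect_equal(estimate_lag(shifted, base, ts),
               -estimate_lag(base, shifted, ts), tolerance = 0.26)
})

test_that("lag estimation rejects gaps, short windows and flat series", {
  ts <- seq(as.POSIXct("2019-06-01", tz = "UTC"), by = 1800, length.out = 6 * 48)
  x <- sin(seq_along(ts) / 5)
  xx <- x
  xx[9] <- NA
  expect_error(estimate_lag(x, xx, ts), "gapless")
  expect_error(estimate_lag(x[1:96], x[1:96], ts[1:96]), "3 days")
  expect_error(estimate_lag(x, rep(1, length(ts)), ts), "flat")
})
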