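#' Spearman rank correlation with tie-aware average ranks
#'
#' Computes rho as the Pearson correlation of average ranks (ties receive the
#' mean of the rank positions they span) after pairwise deletion of missing
#' values, and a p-value from the t approximation
#' `t = rho * sqrt((n-2) / (1-rho^2))` on n-2 degrees of freedom.
#' rho is invariant under strictly monotone transforms of either argument.
#'
#' @param x,y numeric series; pairs with a missing member are dropped.
#' @return A list `rho, p, n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stopf("spearman_cor needs >= 5 paired non-missing values, got %d", n)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stopf("undefined-correlation error: an input is constant (all values tied)")
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Rank-correlation table between daily xylem metrics and the environment
#'
#' For each daily radius response (`daily_max`, `daily_mean`, `daily_min`,
#' and optionally `amplitude`) and each environmental variable (T, VPD and RH
#' max/mean/min, precipitation sum, soil water content), computes the
#' Spearman rho over growing-season days (April-September by default), with
#' significance stars at p < 0.05 / 0.01 / 0.001.
#'
#' @param daily_radius table from [daily_radius_stats()].
#' @param daily_clim table from [daily_climate()].
#' @param season_only restrict to the April-September window?
#' @param include_amplitude add the daily amplitude as a response?
#' @return A long data frame `response, predictor, rho, p, n, stars`.
#' @export
correlation_table <- function(daily_radius, daily_clim, season_only = TRUE,
                              include_amplitude = FALSE) {
  df <- merge(daily_radius, daily_clim, by = "date")
  if (season_only) df <- df[in_growing_season(df$date), , drop = FALSE]
  if (!nrow(df)) stopf("validation error: empty seasonal mask")
  responses <- c(Xyl_max = "daily_max", Xyl_mean = "daily_mean",
                 Xyl_min = "daily_min")
  if (include_amplitude) responses <- c(responses, Xyl_amplitude = "amplitude")
  predictors <- c("t_max", "t_mean", "t_min", "vpd_max", "vpd_mean", "vpd_min",
                  "rh_max", "rh_mean", "rh_min", "p_sum", "swc_mean")
  rows <- list()
  for (r in names(responses)) {
    for (p in predictors) {
      s <- spearman_cor(df[[responses[[r]]]], df[[p]])
      rows[[length(rows) + 1L]] <- data.frame(
        response = r, predictor = p, rho = s$rho, p = s$p, n = s$n,
        stars = signif_stars(s$p))
    }
  }
  do.call(rbind, rows)
}

#' Stepwise multiple regression (forward selection with backward checks)
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' predictor with the smallest partial-F p-value if it is below `alpha_in`,
#' then removes any included predictor whose partial-F p-value exceeds
#' `alpha_out`, iterating to a fixed point. For a single-predictor step the
#' partial F equals the squared coefficient t statistic. Coefficients are
#' non-standardized.
#'
#' @param y numeric response (daily series).
#' @param predictors data frame of candidate predictors (daily series).
#' @param alpha_in entry threshold on the partial-F p-value.
#' @param alpha_out removal threshold (must be >= `alpha_in`).
#' @return A `stepwise_model` list: `selected` (character), `coefficients`
#'   (estimate/SE/t/p incl. intercept), `adj_r_squared`, `f_value`, `df`
#'   (k, n-k-1), `n`, and the underlying `lm` fit.
#' @export
stepwise_regression <- function(y, predictors, alpha_in = 0.05, alpha_out = 0.10) {
  stopifnot(is.data.frame(predictors))
  if (alpha_out < alpha_in) stopf("alpha_out must be >= alpha_in")
  dat <- data.frame(.y = y, predictors, check.names = FALSE)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  pool <- names(predictors)
  n <- nrow(dat)
  if (length(pool) && n < 10L * length(pool)) {
    stopf("data-quantity error: %d complete rows for %d predictors (need >= %d)",
          n, length(pool), 10L * length(pool))
  }
  # guard against perfectly collinear candidate pairs
  if (length(pool) >= 2L) {
    cm <- suppressWarnings(stats::cor(dat[pool]))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 0
    if (any(abs(cm) > 1 - 1e-12)) {
      ij <- sort(which(abs(cm) > 1 - 1e-12, arr.ind = TRUE)[1L, ])
      stopf("collinearity error: predictors '%s' and '%s' are perfectly collinear",
            pool[ij[1L]], pool[ij[2L]])
    }
  }

  fit_of <- function(vars) {
    fml <- if (length(vars)) {
      stats::reformulate(sprintf("`%s`", vars), response = ".y")
    } else {
      .y ~ 1
    }
    stats::lm(fml, data = dat)
  }
  pvals_of <- function(fit, vars) {
    # partial-F p-value of each term given the others = squared-t p-value
    cf <- summary(fit)$coefficients
    out <- stats::setNames(rep(NA_real_, length(vars)), vars)
    rn <- sprintf("`%s`", vars)
    hit <- match(rn, rownames(cf))
    hit2 <- match(vars, rownames(cf))
    idx <- ifelse(is.na(hit), hit2, hit)
    out[] <- cf[idx, 4L]
    out
  }

  selected <- character(0)
  seen <- character(0)
  repeat {
    key <- paste(sort(selected), collapse = "|")
    if (key %in% seen) break   # cycle guard
    seen <- c(seen, key)
    changed <- FALSE
    # forward step
    cand <- setdiff(pool, selected)
    if (length(cand)) {
      pin <- vapply(cand, function(v) {
        f <- fit_of(c(selected, v))
        pvals_of(f, c(selected, v))[[v]]
      }, numeric(1))
      pin[is.na(pin)] <- Inf
      if (min(pin) < alpha_in) {
        selected <- c(selected, cand[which.min(pin)])
        changed <- TRUE
      }
    }
    # backward checks
    repeat {
      if (!length(selected)) break
      pout <- pvals_of(fit_of(selected), selected)
      pout[is.na(pout)] <- Inf
      worst <- which.max(pout)
      if (pout[worst] > alpha_out) {
        selected <- selected[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  fit <- fit_of(selected)
  sm <- summary(fit)
  cf <- sm$coefficients
  rownames(cf) <- gsub("`", "", rownames(cf))
  fstat <- sm$fstatistic
  out <- list(selected = selected,
              coefficients = data.frame(term = rownames(cf),
                                        estimate = cf[, 1L], se = cf[, 2L],
                                        t = cf[, 3L], p = cf[, 4L],
                                        row.names = NULL),
              adj_r_squared = if (length(selected)) sm$adj.r.squared else 0,
              f_value = if (is.null(fstat)) NA_real_ else unname(fstat[1L]),
              df = if (is.null(fstat)) c(0L, n - 1L) else unname(fstat[2:3]),
              n = n, fit = fit)
  class(out) <- "stepwise_model"
  out
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("<stepwise_model> %s; adj R^2 = %.3f; F(%g, %g) = %.2f; n = %d\n",
              if (length(x$selected)) paste(x$selected, collapse = " + ")
              else "(intercept only)",
              x$adj_r_squared, x$df[1L], x$df[2L], x$f_value, x$n))
  invisible(x)
}

#' Logarithmic fit of daily amplitude against daily maximum VPD
#'
#' Least-squares fit of `amplitude = a + b * ln(vpd_max)`; days with
#' `vpd_max <= 0.05` kPa are excluded (log guard). The saturating shape of
#' the canopy response makes this fit outperform a straight line whenever
#' conductance declines with VPD; the R-squared of the competing linear fit
#' is returned for that comparison.
#'
#' @param amplitude daily amplitude series (um).
#' @param vpd_max daily maximum VPD series (kPa).
#' @return A list `a, b, se_a, se_b, r_squared, r_squared_linear, n`.
#' @export
fit_log_amplitude <- function(amplitude, vpd_max) {
  ok <- !is.na(amplitude) & !is.na(vpd_max) & vpd_max > 0.05
  if (sum(ok) < 10L) {
    stopf("data-quantity error: %d valid days for the log fit (need >= 10)", sum(ok))
  }
  a <- amplitude[ok]; v <- vpd_max[ok]
  flog <- stats::lm(a ~ log(v))
  flin <- stats::lm(a ~ v)
  cf <- summary(flog)$coefficients
  list(a = unname(cf[1L, 1L]), b = unname(cf[2L, 1L]),
       se_a = unname(cf[1L, 2L]), se_b = unname(cf[2L, 2L]),
       r_squared = summary(flog)$r.squared,
       r_squared_linear = summary(flin)$r.squared,
       n = sum(ok))
}

#' Lag between two 30-min series by cross-correlation
#'
#' Both series are first high-pass filtered by removing each calendar day's
#' mean, then the lag maximizing the Pearson cross-correlation of `y`
#' against `x` is located over `+/- max_lag_hours` at 30-min resolution and
#' refined by parabolic interpolation around the discrete peak. Positive
#' values mean `y` lags behind `x` (e.g. inner bark behind xylem).
#'
#' @param x,y numeric 30-min series on a common gapless window of >= 3 days.
#' @param timestamps POSIXct grid shared by both series.
#' @param max_lag_hours half-width of the searched lag window (hours).
#' @return Lag in hours (positive: `y` lags `x`).
#' @export
estimate_lag <- function(x, y, timestamps, max_lag_hours = 12) {
  n <- length(x)
  if (length(y) != n || length(timestamps) != n) stopf("series lengths differ")
  if (anyNA(x) || anyNA(y)) {
    stopf("estimation error: estimate_lag requires a gapless common window")
  }
  if (n < 3L * STEPS_PER_DAY) {
    stopf("estimation error: window shorter than 3 days (%d records)", n)
  }
  dts <- grid_date(timestamps)
  hp <- function(v) v - stats::ave(v, dts)
  xh <- hp(x); yh <- hp(y)
  if (stats::sd(xh) == 0 || stats::sd(yh) == 0) {
    stopf("estimation error: flat series after high-pass filtering")
  }
  kmax <- round(max_lag_hours / DT_HOURS)
  lags <- (-kmax):kmax
  cc <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(xh[seq_len(n - k)], yh[seq_len(n - k) + k])
    else stats::cor(xh[seq_len(n + k) - k], yh[seq_len(n + k)])
  }, numeric(1))
  i <- which.max(cc)
  delta <- 0
  if (i > 1L && i < length(cc)) {
    den <- cc[i - 1L] - 2 * cc[i] + cc[i + 1L]
    if (den < 0) delta <- 0.5 * (cc[i - 1L] - cc[i + 1L]) / den
  }
  (lags[i] + delta) * DT_HOURS
}

#' Bark-to-xylem daily amplitude ratio
#'
#' Ratio of the mean daily amplitude of the inner bark to that of the xylem
#' over days where both are valid (growing season by default). On a passive
#' hydraulic stem this estimates the elasticity ratio `eps_b / eps_x`,
#' slightly shrunk by the low-pass attenuation of the storage compartment.
#'
#' @param daily_innerbark,daily_xylem tables from [daily_radius_stats()].
#' @param season_only restrict to April-September days?
#' @return A list `ratio, n`.
#' @export
amplitude_ratio <- function(daily_innerbark, daily_xylem, season_only = TRUE) {
  df <- merge(daily_innerbark[, c("date", "amplitude")],
              daily_xylem[, c("date", "amplitude")],
              by = "date", suffixes = c("_ib", "_xyl"))
  if (season_only) df <- df[in_growing_season(df$date), , drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 5L) stopf("data-quantity error: %d paired valid days", nrow(df))
  list(ratio = mean(df$amplitude_ib) / mean(df$amplitude_xyl), n = nrow(df))
}
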