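# Independent brute-force oracles, deliberately written with different
# machinery than the package implementations they check.

# Average ranks by explicit counting: rank = (#smaller) + (#equal + 1)/2.
brute_ranks <- function(v) {
  n <- length(v)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }
  r
}

# Spearman rho as Pearson on brute-force ranks, via explicit sums.
brute_spearman <- function(x, y) {
  rx <- brute_ranks(x)
  ry <- brute_ranks(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Forward-with-removal stepwise selection computed from residual sums of
# squares and the partial-F distribution directly (no coefficient t-tests).
oracle_stepwise <- function(y, X, alpha_in = 0.05, alpha_out = 0.10) {
  dat <- cbind(.y = y, X)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  rss_of <- function(vars) {
    M <- cbind(Intercept = 1, as.matrix(dat[vars]))
    fit <- stats::lm.fit(M, dat$.y)
    sum(fit$residuals^2)
  }
  partial_p <- function(without, with_vars) {
    rss0 <- rss_of(without)
    rss1 <- rss_of(with_vars)
    df2 <- n - length(with_vars) - 1L
    f <- (rss0 - rss1) / (rss1 / df2)
    stats::pf(f, 1L, df2, lower.tail = FALSE)
  }
  selected <- character(0)
  seen <- character(0)
  repeat {
    key <- paste(sort(selected), collapse = "|")
    if (key %in% seen) break
    seen <- c(seen, key)
    changed <- FALSE
    cand <- setdiff(names(X), selected)
    if (length(cand)) {
      pv <- vapply(cand, function(v) partial_p(selected, c(selected, v)), 0)
      pv[is.na(pv)] <- Inf
      if (min(pv) < alpha_in) {
        selected <- c(selected, cand[which.min(pv)])
        changed <- TRUE
      }
    }
    repeat {
      if (!length(selected)) break
      pv <- vapply(selected,
                   function(v) partial_p(setdiff(selected, v), selected), 0)
      pv[is.na(pv)] <- Inf
      worst <- which.max(pv)
      if (pv[worst] > alpha_out) {
        selected <- selected[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  sort(selected)
}
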