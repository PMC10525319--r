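#' Parameters of the two-compartment stem hydraulics model
#'
#' The stem is modelled as a transpiration-driven passive hydraulic system
#' with two compartments: the xylem water column (a low-capacitance node at
#' water potential psi_x) connected to the soil through resistance `r_soil`,
#' and an elastic storage compartment (inner bark: living phloem, cambium,
#' parenchyma) at potential psi_s, exchanging water with the xylem through
#' resistance `r_stor` and holding capacitance `c_stor`. Transpiration E pulls
#' water out of the xylem node during daylight; storage discharges into the
#' xylem with first-order time constant tau = `r_stor * c_stor`, which sets
#' how far inner-bark shrinkage lags behind xylem shrinkage. Radii map
#' linearly onto potentials through tissue elasticities; the lignified xylem
#' (`eps_x`) is roughly ten times stiffer than the inner bark (`eps_b`),
#' which is what makes the inner-bark diurnal amplitude ~10x the xylem one.
#'
#' @param g_max canopy transpiration conductance (unit water h-1 kPa-1 at
#'   full sun, before VPD saturation).
#' @param vpd_sat half-saturation VPD (kPa) of the canopy-conductance decline;
#'   E = g_max * s(SR) * VPD / (1 + VPD / vpd_sat) saturates above ~3 kPa.
#' @param r_soil soil-to-xylem flow resistance (MPa per unit flux).
#' @param r_stor storage-to-xylem exchange resistance (MPa per unit flux).
#' @param c_stor storage capacitance (unit water per MPa);
#'   tau = r_stor * c_stor (hours) is the bark-behind-xylem lag scale.
#' @param eps_x,eps_b radial elasticity of xylem and inner bark (um MPa-1);
#'   default ratio 10.
#' @param k_soilpsi decline of soil water potential per vol % of soil-water
#'   deficit below `swc_max` (MPa per vol %).
#' @param growth_total seasonal radial growth of the inner bark (um).
#' @param growth_midpoint_doy,growth_rate Gompertz growth-curve midpoint
#'   (day of year) and rate (day-1).
#' @param alpha_x,alpha_b thermal-expansion artifact added to the measured
#'   xylem and over-bark records (um per deg C).
#' @param noise_sd sensor noise standard deviation (um).
#' @param gap_fraction probability in `[0, 1)` that a 30-min record is lost.
#' @param swc_max soil water content at which soil water potential is zero
#'   (vol %); matches the weather generator's `swc_max`.
#' @param seed integer RNG seed for noise and gap placement.
#' @return A `hydraulic_params` list.
#' @export
hydraulic_params <- function(g_max = 0.3, vpd_sat = 1.2,
                             r_soil = 8, r_stor = 4, c_stor = 0.5,
                             eps_x = 30, eps_b = 10 * eps_x,
                             k_soilpsi = 0.04,
                             growth_total = 700, growth_midpoint_doy = 170,
                             growth_rate = 0.04,
                             alpha_x = 1.08, alpha_b = 0.2,
                             noise_sd = 0.5, gap_fraction = 0.02,
                             swc_max = 33.5, seed = 1L) {
  par <- list(g_max = g_max, vpd_sat = vpd_sat, r_soil = r_soil,
              r_stor = r_stor, c_stor = c_stor, eps_x = eps_x, eps_b = eps_b,
              k_soilpsi = k_soilpsi, growth_total = growth_total,
              growth_midpoint_doy = growth_midpoint_doy,
              growth_rate = growth_rate, alpha_x = alpha_x, alpha_b = alpha_b,
              noise_sd = noise_sd, gap_fraction = gap_fraction,
              swc_max = swc_max, seed = as.integer(seed))
  validate_hydraulic_params(par)
  class(par) <- "hydraulic_params"
  par
}

validate_hydraulic_params <- function(par) {
  for (nm in c("r_soil", "r_stor", "c_stor", "eps_x", "eps_b")) {
    check_field(par[[nm]], nm, lo = .Machine$double.eps)
  }
  check_field(par$g_max, "g_max", 0)
  check_field(par$vpd_sat, "vpd_sat", .Machine$double.eps)
  check_field(par$k_soilpsi, "k_soilpsi", 0)
  check_field(par$growth_total, "growth_total", 0)
  check_field(par$noise_sd, "noise_sd", 0)
  check_field(par$gap_fraction, "gap_fraction", 0, 1 - 1e-9)
  invisible(par)
}

#' Cumulative Gompertz radial-growth curve
#'
#' Intra-annual growth follows a Gompertz sigmoid of day-of-year; across
#' calendar years the completed seasons' totals accumulate.
#' @noRd
growth_curve <- function(timestamps, par) {
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  year0 <- lt$year[1L]
  doy <- lt$yday + 1L
  within <- exp(-exp(-par$growth_rate * (doy - par$growth_midpoint_doy)))
  par$growth_total * ((lt$year - year0) + within)
}

#' Simulate dendrometer traces from a climate record
#'
#' Runs the two-compartment stem model forward over a gap-free climate trace
#' at the 30-min cadence (explicit Euler for the storage pool; the xylem node
#' is solved quasi-steadily at every step):
#' \describe{
#'   \item{transpiration}{`E = g_max * s(SR) * VPD / (1 + VPD/vpd_sat)` with
#'     `s(SR) = min(SR / sr_ref, 1)`; zero at night since SR = 0.}
#'   \item{soil}{`psi_soil = -k_soilpsi * (swc_max - SWC)`.}
#'   \item{xylem node}{`(psi_soil - psi_x)/r_soil + (psi_s - psi_x)/r_stor = E`.}
#'   \item{storage}{`q = (psi_s - psi_x)/r_stor`; `W <- W - q*dt`;
#'     `psi_s = psi_s0 + (W - W0)/c_stor`.}
#'   \item{radii}{true xylem radius `r_x = eps_x*(psi_x - psi_x0)`; bark
#'     thickness `b = G(t) + eps_b*(psi_s - psi_s0)`; measured xylem =
#'     `r_x + alpha_x*T + noise`; measured over-bark =
#'     `r_x + b + alpha_b*T + noise`; records dropped at `gap_fraction`.}
#' }
#'
#' @param climate a gap-free [climate_trace()].
#' @param params a [hydraulic_params()].
#' @param tree_id label for the returned traces.
#' @param sr_ref solar radiation (W m-2) at which light response saturates.
#' @return A list with elements `overbark` and `xylem` ([sensor_trace()]s of
#'   the measured records, uncorrected) and `truth` (a `sim_truth` list:
#'   per-step data frame of the unobserved states `psi_soil, psi_x, psi_s,
#'   W, q, E`, the noise/artifact-free radii `r_x_true, b_true`, the growth
#'   curve, and the `hydraulic_params` used).
#' @export
simulate_stem <- function(climate, params = hydraulic_params(),
                          tree_id = "sim1", sr_ref = 250) {
  if (!inherits(climate, "climate_trace")) stopf("climate must be a climate_trace")
  if (!inherits(params, "hydraulic_params")) params <- do.call(hydraulic_params, params)
  validate_hydraulic_params(params)
  cc <- c("t_air", "rh", "sr", "p", "swc", "vpd")
  if (anyNA(climate[cc])) {
    stopf("precondition error: climate trace contains gaps; simulate_stem needs a gap-free grid")
  }
  withr::with_seed(params$seed, simulate_stem_impl(climate, params, tree_id, sr_ref))
}

simulate_stem_impl <- function(climate, par, tree_id, sr_ref) {
  n <- nrow(climate)
  ts <- climate$timestamp
  dt <- DT_HOURS

  s_light <- pmin(climate$sr / sr_ref, 1)
  E <- par$g_max * s_light * climate$vpd / (1 + climate$vpd / par$vpd_sat)
  psi_soil <- -par$k_soilpsi * (par$swc_max - climate$swc)

  a <- 1 / par$r_soil
  b <- 1 / par$r_stor
  denom <- a + b

  psi_x <- numeric(n); psi_s <- numeric(n); W <- numeric(n); q <- numeric(n)
  psi_s0 <- psi_soil[1L]
  W0 <- 0
  ps <- psi_s0
  w <- W0
  px_prev <- NA_real_
  for (i in seq_len(n)) {
    px <- (a * psi_soil[i] + b * ps - E[i]) / denom
    if (!is.na(px_prev) && abs(px - px_prev) > 1) {
      stopf(paste("numerical error: xylem potential changed by %.2f MPa in one",
                  "30-min step; reduce the time step or increase r_soil/r_stor"),
            abs(px - px_prev))
    }
    qi <- (ps - px) / par$r_stor
    w <- w - qi * dt
    psi_x[i] <- px; psi_s[i] <- ps; W[i] <- w; q[i] <- qi
    ps <- psi_s0 + (w - W0) / par$c_stor
    px_prev <- px
  }

  psi_x0 <- psi_x[1L]
  G <- growth_curve(ts, par)
  G <- G - G[1L]
  r_x_true <- par$eps_x * (psi_x - psi_x0)
  b_true <- G + par$eps_b * (psi_s - psi_s0)

  noise_x <- stats::rnorm(n, 0, par$noise_sd)
  noise_o <- stats::rnorm(n, 0, par$noise_sd)
  meas_x <- r_x_true + par$alpha_x * climate$t_air + noise_x
  meas_o <- r_x_true + b_true + par$alpha_b * climate$t_air + noise_o
  gap_x <- stats::runif(n) < par$gap_fraction
  gap_o <- stats::runif(n) < par$gap_fraction
  meas_x[gap_x] <- NA_real_
  meas_o[gap_o] <- NA_real_

  truth <- list(
    states = data.frame(timestamp = ts, psi_soil = psi_soil, psi_x = psi_x,
                        psi_s = psi_s, W = W, q = q, E = E,
                        growth = G, r_x_true = r_x_true, b_true = b_true),
    params = par)
  class(truth) <- "sim_truth"

  # water balance closure: W is updated exactly by -q*dt each step
  turnover <- sum(abs(truth$states$q)) * dt
  drift <- abs((W[n] - W0) + sum(q) * dt)
  if (turnover > 0 && drift > 1e-6 * turnover) {
    stopf("internal error: water balance drift %.3g exceeds tolerance", drift)
  }

  list(overbark = sensor_trace(ts, meas_o, tree_id, "overbark", corrected = FALSE),
       xylem = sensor_trace(ts, meas_x, tree_id, "xylem", corrected = FALSE),
       truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  st <- x$states
  cat(sprintf("<sim_truth> %d steps; psi_x in [%.2f, %.2f] MPa; growth %.0f um\n",
              nrow(st), min(st$psi_x), max(st$psi_x), max(st$growth)))
  invisible(x)
}

#' Simulate a small stand of trees sharing one climate record
#'
#' Each tree gets a derived seed (noise and gap placement differ) while the
#' hydraulic parameters and climate forcing are shared.
#' @param climate a [climate_trace()].
#' @param params a [hydraulic_params()]; `params$seed` seeds the stand.
#' @param n_trees number of trees.
#' @return List of per-tree `simulate_stem()` results, names `tree1..treeN`.
#' @export
simulate_stand <- function(climate, params = hydraulic_params(), n_trees = 4L) {
  seeds <- derive_seeds(params$seed, n_trees)
  out <- lapply(seq_len(n_trees), function(i) {
    p <- params
    p$seed <- seeds[i]
    simulate_stem(climate, p, tree_id = paste0("tree", i))
  })
  names(out) <- paste0("tree", seq_len(n_trees))
  out
}
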