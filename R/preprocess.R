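#' Vapour pressure deficit from air temperature and relative humidity
#'
#' Magnus saturation-vapour-pressure form:
#' `VPD = 0.6108 * exp(17.27 * T / (T + 237.3)) * (1 - RH/100)` (kPa).
#' VPD is zero in saturated air (RH = 100) and strictly increases with T at
#' fixed RH.
#'
#' @param t_air air temperature series (deg C, > -40).
#' @param rh relative humidity series (%, in `[0, 100]`).
#' @param timestamps optional; used to name offending records in errors.
#' @return Numeric VPD series (kPa), `NA` where either input is `NA`.
#' @examples
#' compute_vpd(25, 50)  # ~1.584 kPa
#' @export
compute_vpd <- function(t_air, rh, timestamps = NULL) {
  if (length(t_air) != length(rh)) {
    stopf("t_air and rh lengths differ (%d vs %d)", length(t_air), length(rh))
  }
  bad <- which(!is.na(rh) & (rh < 0 | rh > 100))
  if (length(bad)) {
    lab <- if (!is.null(timestamps)) {
      paste(format(timestamps[utils::head(bad, 5L)]), collapse = ", ")
    } else {
      paste("indices", paste(utils::head(bad, 5L), collapse = ", "))
    }
    stopf("validation error: RH outside [0, 100] at %d record(s): %s",
          length(bad), lab)
  }
  if (any(t_air <= -40, na.rm = TRUE)) {
    stopf("validation error: t_air at or below -40 deg C")
  }
  es <- 0.6108 * exp(17.27 * t_air / (t_air + 237.3))
  pmax(es * (1 - rh / 100), 0)
}

#' Thermal-expansion correction defaults
#'
#' Point-dendrometer records carry a thermal artifact from the sensor body
#' (and, for xylem sensors, the mounting screw inserted into the sapwood).
#' The over-bark sensor is corrected by the sensor coefficient alone
#' (0.2 um per deg C); the xylem sensor by the combined constant
#' 1.08 um per deg C. Material constants are recorded for documentation:
#' steel 13.9e-6 per deg C, moist wood 7.9e-6 per deg C, sensor
#' 0.2 um per deg C; the xylem coefficient is used as given, not re-derived.
#'
#' @param coeff_bark over-bark correction coefficient (um per deg C).
#' @param coeff_xylem xylem correction coefficient (um per deg C).
#' @param reference_temperature `"first_observation"` or a fixed numeric
#'   value (deg C); only radius *variations* matter downstream, so the
#'   choice shifts the corrected trace by a constant.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(coeff_bark = 0.2, coeff_xylem = 1.08,
                              reference_temperature = "first_observation") {
  check_field(coeff_bark, "coeff_bark", 0)
  check_field(coeff_xylem, "coeff_xylem", 0)
  structure(list(coeff_bark = coeff_bark, coeff_xylem = coeff_xylem,
                 reference_temperature = reference_temperature,
                 material_constants = c(steel_perC = 13.9e-6,
                                        moist_wood_perC = 7.9e-6,
                                        sensor_um_perC = 0.2)),
            class = "preprocess_config")
}

#' Remove the thermal-expansion artifact from a sensor trace
#'
#' `corrected = raw - coeff * (T - T_ref)`, with the coefficient chosen by
#' sensor position (over-bark: `coeff_bark`; xylem: `coeff_xylem`). A warmer
#' sensor/screw inflates the raw reading, so the expansion is subtracted.
#' Missing radii stay missing; the trace's `corrected` flag is set.
#'
#' @param trace an uncorrected [sensor_trace()] at position `overbark` or
#'   `xylem`.
#' @param t_air air temperature aligned to the trace: either a numeric vector
#'   of the same length or a [climate_trace()] covering the same timestamps.
#' @param config a [preprocess_config()].
#' @return The corrected [sensor_trace()].
#' @export
thermal_correct <- function(trace, t_air, config = preprocess_config()) {
  if (!inherits(trace, "sensor_trace")) stopf("trace must be a sensor_trace")
  if (isTRUE(attr(trace, "corrected"))) {
    stopf("state error: trace is already thermally corrected")
  }
  pos <- attr(trace, "position")
  coeff <- switch(pos,
                  overbark = config$coeff_bark,
                  xylem = config$coeff_xylem,
                  stopf("thermal correction applies to overbark or xylem sensors, not '%s'", pos))
  if (inherits(t_air, "climate_trace")) {
    idx <- match(as.numeric(trace$timestamp), as.numeric(t_air$timestamp))
    if (anyNA(idx)) {
      stopf("alignment error: %d trace timestamps missing from climate record",
            sum(is.na(idx)))
    }
    t_air <- t_air$t_air[idx]
  }
  if (length(t_air) != nrow(trace)) {
    stopf("alignment error: temperature length %d != trace length %d",
          length(t_air), nrow(trace))
  }
  t_ref <- config$reference_temperature
  if (identical(t_ref, "first_observation")) {
    t_ref <- t_air[which(!is.na(trace$radius) & !is.na(t_air))[1L]]
    if (is.na(t_ref)) stopf("alignment error: no overlapping valid records")
  } else {
    check_field(t_ref, "reference_temperature", -60, 60)
  }
  out <- trace
  out$radius <- trace$radius - coeff * (t_air - t_ref)
  attr(out, "corrected") <- TRUE
  out
}

#' Decompose an over-bark record into its inner-bark component
#'
#' The inner-bark variation (living phloem + cambium + parenchyma) is the
#' over-bark record minus the xylem record, elementwise on the shared grid.
#' Both inputs must already be thermally corrected and belong to the same
#' tree. The result is missing wherever either input is missing, so
#' `innerbark + xylem` reconstructs `overbark` exactly where both exist.
#'
#' @param overbark,xylem corrected [sensor_trace()]s of one tree.
#' @return An inner-bark [sensor_trace()] (flagged corrected).
#' @export
decompose_inner_bark <- function(overbark, xylem) {
  for (tr in list(overbark, xylem)) {
    if (!inherits(tr, "sensor_trace")) stopf("inputs must be sensor_traces")
    if (!isTRUE(attr(tr, "corrected"))) {
      stopf("state error: decompose requires thermally corrected traces")
    }
  }
  if (!identical(attr(overbark, "tree_id"), attr(xylem, "tree_id"))) {
    stopf("identity error: traces belong to different trees ('%s' vs '%s')",
          attr(overbark, "tree_id"), attr(xylem, "tree_id"))
  }
  if (!identical(as.numeric(overbark$timestamp), as.numeric(xylem$timestamp))) {
    stopf("alignment error: over-bark and xylem grids differ")
  }
  sensor_trace(overbark$timestamp, overbark$radius - xylem$radius,
               tree_id = attr(overbark, "tree_id"), position = "innerbark",
               corrected = TRUE)
}

#' Average sensor traces across trees
#'
#' Computes the per-timestamp mean and standard error over trees with data
#' present. By default each trace is first re-zeroed to its first valid
#' reading so that trees of different absolute radius can be averaged;
#' `rezero = FALSE` averages the raw values.
#'
#' @param traces list of >= 2 [sensor_trace()]s, same position.
#' @param rezero subtract each trace's first valid reading first?
#' @return A data frame `timestamp, mean, se, n_trees` carrying the common
#'   position as attribute; `se = sd / sqrt(n)` over contributing trees.
#' @export
aggregate_trees <- function(traces, rezero = TRUE) {
  if (!length(traces)) stopf("validation error: empty trace list")
  if (length(traces) < 2L) stopf("validation error: need >= 2 traces to aggregate")
  pos <- unique(vapply(traces, function(tr) attr(tr, "position"), ""))
  if (length(pos) != 1L) {
    stopf("validation error: mixed sensor positions (%s)", paste(pos, collapse = ", "))
  }
  ts0 <- traces[[1L]]$timestamp
  mat <- vapply(traces, function(tr) {
    if (!identical(as.numeric(tr$timestamp), as.numeric(ts0))) {
      stopf("alignment error: traces are on different grids")
    }
    r <- tr$radius
    if (rezero) r <- r - r[which(!is.na(r))[1L]]
    r
  }, numeric(length(ts0)))
  n <- rowSums(!is.na(mat))
  m <- rowMeans(mat, na.rm = TRUE)
  m[n == 0L] <- NA_real_
  sdv <- apply(mat, 1L, stats::sd, na.rm = TRUE)
  se <- ifelse(n >= 2L, sdv / sqrt(n), NA_real_)
  out <- data.frame(timestamp = ts0, mean = m, se = se, n_trees = n)
  attr(out, "position") <- pos
  out
}

#' Mean-trace view of an aggregate as a sensor_trace
#' @param agg result of [aggregate_trees()].
#' @param tree_id label for the synthetic "mean tree".
#' @return A corrected [sensor_trace()] of the mean series.
#' @export
aggregate_as_trace <- function(agg, tree_id = "mean") {
  sensor_trace(agg$timestamp, agg$mean, tree_id = tree_id,
               position = attr(agg, "position"), corrected = TRUE)
}
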