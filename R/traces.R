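#' Sensor trace: one 30-min radius series for one tree and sensor position
#'
#' A `sensor_trace` is a data frame with columns `timestamp` (POSIXct, regular
#' 30-min grid, local standard time) and `radius` (micrometres, `NA` allowed
#' for logger gaps), carrying the tree identity, the sensor position and a
#' flag recording whether thermal-expansion correction has been applied.
#'
#' @param timestamp POSIXct vector on a strict 30-min grid.
#' @param radius numeric radius values in micrometres; `NA` marks gaps.
#' @param tree_id character label of the tree.
#' @param position one of `"overbark"`, `"xylem"`, `"innerbark"`.
#' @param corrected logical; has thermal correction been applied?
#' @return An object of class `sensor_trace` (a data frame).
#' @examples
#' ts <- seq(as.POSIXct("2019-04-01", tz = "UTC"), by = 1800, length.out = 48)
#' tr <- sensor_trace(ts, sin(seq_len(48) / 8), tree_id = "t1", position = "xylem")
#' @export
sensor_trace <- function(timestamp, radius, tree_id, position,
                         corrected = FALSE) {
  position <- match.arg(position, c("overbark", "xylem", "innerbark"))
  if (length(timestamp) != length(radius)) {
    stopf("timestamp and radius lengths differ (%d vs %d)",
          length(timestamp), length(radius))
  }
  assert_grid(timestamp, "sensor_trace timestamps")
  radius <- as.numeric(radius)
  if (any(is.infinite(radius), na.rm = TRUE)) {
    stopf("radius contains non-finite values other than NA")
  }
  out <- data.frame(timestamp = timestamp, radius = radius)
  attr(out, "tree_id") <- as.character(tree_id)
  attr(out, "position") <- position
  attr(out, "corrected") <- isTRUE(corrected)
  class(out) <- c("sensor_trace", "data.frame")
  out
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("<sensor_trace> tree %s, %s, %d records (%s .. %s), %scorrected\n",
              attr(x, "tree_id"), attr(x, "position"), nrow(x),
              format(x$timestamp[1L]), format(x$timestamp[nrow(x)]),
              if (attr(x, "corrected")) "" else "not "))
  invisible(x)
}

#' Climate trace: 30-min microclimate series with derived VPD
#'
#' Columns: `timestamp`, `t_air` (deg C), `rh` (%), `sr` (W m-2), `p`
#' (mm per 30-min interval), `swc` (vol %), `vpd` (kPa, derived from
#' `t_air` and `rh` via [compute_vpd()]).
#'
#' @param timestamp POSIXct 30-min grid.
#' @param t_air,rh,sr,p,swc numeric series (see above for units).
#' @param vpd optional; recomputed from `t_air`/`rh` when `NULL`.
#' @return An object of class `climate_trace` (a data frame).
#' @export
climate_trace <- function(timestamp, t_air, rh, sr, p, swc, vpd = NULL) {
  assert_grid(timestamp, "climate_trace timestamps")
  n <- length(timestamp)
  for (nm in c("t_air", "rh", "sr", "p", "swc")) {
    v <- get(nm)
    if (length(v) != n) stopf("column '%s' length %d != %d", nm, length(v), n)
  }
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) {
    stopf("validation error: rh outside [0, 100]")
  }
  if (any(p < 0, na.rm = TRUE)) stopf("validation error: negative precipitation")
  if (any(sr < 0, na.rm = TRUE)) stopf("validation error: negative solar radiation")
  if (is.null(vpd)) vpd <- compute_vpd(t_air, rh, timestamp)
  out <- data.frame(timestamp = timestamp, t_air = t_air, rh = rh, sr = sr,
                    p = p, swc = swc, vpd = vpd)
  class(out) <- c("climate_trace", "data.frame")
  out
}

#' @export
print.climate_trace <- function(x, ...) {
  cat(sprintf("<climate_trace> %d records (%s .. %s)\n", nrow(x),
              format(x$timestamp[1L]), format(x$timestamp[nrow(x)])))
  invisible(x)
}

TS_FMT <- "%Y-%m-%dT%H:%M:%S"

parse_ts <- function(x) {
  out <- as.POSIXct(x, tz = "UTC", format = TS_FMT)
  if (anyNA(out)) out2 <- as.POSIXct(x, tz = "UTC") else out2 <- out
  if (anyNA(out) && !anyNA(out2)) return(out2)
  if (anyNA(out)) stopf("unparseable timestamps (expected ISO 8601), e.g. '%s'",
                        x[which(is.na(out))[1L]])
  out
}

#' Read a long-format dendrometer CSV into sensor traces
#'
#' Expected columns: `timestamp` (ISO 8601, local standard time), `tree_id`,
#' `position` (`overbark` or `xylem`), `radius_um`. A `col_map` named list can
#' remap differently-named columns of a foreign deposit, e.g.
#' `list(timestamp = "time", radius_um = "value")`.
#'
#' @param path CSV file path.
#' @param col_map optional named list mapping expected names to file columns.
#' @param corrected whether the stored radii are already thermally corrected.
#' @return A list of [sensor_trace()] objects, one per (tree, position).
#' @export
read_dendro_csv <- function(path, col_map = NULL, corrected = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("timestamp", "tree_id", "position", "radius_um")
  for (nm in want) {
    src <- col_map[[nm]] %||% nm
    if (!src %in% names(df)) {
      stopf("dendrometer CSV schema violation: missing column '%s'", src)
    }
    if (src != nm) df[[nm]] <- df[[src]]
  }
  df$timestamp <- parse_ts(df$timestamp)
  key <- interaction(df$tree_id, df$position, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$timestamp), ]
    sensor_trace(g$timestamp, g$radius_um, tree_id = g$tree_id[1L],
                 position = g$position[1L], corrected = corrected)
  })
}

#' Write sensor traces to a long-format dendrometer CSV
#' @param traces list of [sensor_trace()] objects.
#' @param path output CSV path.
#' @export
write_dendro_csv <- function(traces, path) {
  if (inherits(traces, "sensor_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(timestamp = format(tr$timestamp, TS_FMT),
               tree_id = attr(tr, "tree_id"),
               position = attr(tr, "position"),
               radius_um = tr$radius)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a climate CSV into a climate trace
#'
#' Expected columns: `timestamp, t_air_c, rh_pct, sr_wm2, p_mm, swc_volpct`.
#' VPD is derived on read.
#' @inheritParams read_dendro_csv
#' @return A [climate_trace()].
#' @export
read_climate_csv <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("timestamp", "t_air_c", "rh_pct", "sr_wm2", "p_mm", "swc_volpct")
  for (nm in want) {
    src <- col_map[[nm]] %||% nm
    if (!src %in% names(df)) {
      stopf("climate CSV schema violation: missing column '%s'", src)
    }
    if (src != nm) df[[nm]] <- df[[src]]
  }
  climate_trace(parse_ts(df$timestamp), df$t_air_c, df$rh_pct, df$sr_wm2,
                df$p_mm, df$swc_volpct)
}

#' Write a climate trace to CSV
#' @param climate a [climate_trace()].
#' @param path output CSV path.
#' @export
write_climate_csv <- function(climate, path) {
  out <- data.frame(timestamp = format(climate$timestamp, TS_FMT),
                    t_air_c = climate$t_air, rh_pct = climate$rh,
                    sr_wm2 = climate$sr, p_mm = climate$p,
                    swc_volpct = climate$swc, vpd_kpa = climate$vpd)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
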