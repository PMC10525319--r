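#' Find the longest window where two 30-min series are both complete
#' @noRd
longest_complete_window <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  r <- rle(ok)
  if (!any(r$values)) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  seq.int(starts[best], ends[best])
}

#' Xylem-phloem coupling report
#'
#' Runs the statistical stage end-to-end on corrected tree-mean traces:
#' residual coupling between detrended xylem and inner-bark daily means
#' (Spearman), the daily-metric vs environment rank-correlation table, one
#' stepwise regression per xylem response (daily max / mean / min) over the
#' full environmental pool, the logarithmic amplitude-VPD fit with its
#' linear competitor and per-variable amplitude correlations, the
#' cross-correlation lag of inner bark behind xylem, and the bark:xylem
#' daily amplitude ratio.
#'
#' @param xylem,innerbark corrected [sensor_trace()]s (typically tree means).
#' @param climate a [climate_trace()] on the same grid.
#' @param cutoff_days low-pass cutoff for the residual-coupling detrend.
#' @param min_coverage valid-day threshold for daily statistics.
#' @param alpha_in,alpha_out stepwise entry/removal thresholds.
#' @param max_lag_hours lag search half-width.
#' @param season_only restrict statistics to April-September days?
#' @return A `coupling_report` list with elements `residual_coupling`,
#'   `correlation_matrix`, `stepwise_models`, `amplitude_fits`, `lag_hours`,
#'   `amplitude_ratio`, plus the daily tables used.
#' @export
coupling_report <- function(xylem, innerbark, climate,
                            cutoff_days = 10, min_coverage = 0.9,
                            alpha_in = 0.05, alpha_out = 0.10,
                            max_lag_hours = 12, season_only = TRUE) {
  d_xyl <- daily_radius_stats(xylem, min_coverage)
  d_ib <- daily_radius_stats(innerbark, min_coverage)
  d_clim <- daily_climate(climate)

  # residual coupling on detrended daily means (common daily grid)
  days <- merge(d_xyl[, c("date", "daily_mean")], d_ib[, c("date", "daily_mean")],
                by = "date", suffixes = c("_xyl", "_ib"))
  full <- data.frame(date = seq(min(days$date), max(days$date), by = 1L))
  days <- merge(full, days, by = "date", all.x = TRUE)
  res_x <- residualize(days$daily_mean_xyl, cutoff_days, days$date)
  res_b <- residualize(days$daily_mean_ib, cutoff_days, days$date)
  mask <- if (season_only) in_growing_season(days$date) else rep(TRUE, nrow(days))
  rc <- spearman_cor(res_x$residual[mask], res_b$residual[mask])

  ctab <- correlation_table(d_xyl, d_clim, season_only = season_only)

  sdat <- merge(d_xyl, d_clim, by = "date")
  if (season_only) sdat <- sdat[in_growing_season(sdat$date), , drop = FALSE]
  pool <- sdat[, c("t_max", "t_mean", "t_min", "vpd_max", "vpd_mean", "vpd_min",
                   "rh_max", "rh_mean", "rh_min", "p_sum", "swc_mean")]
  steps <- lapply(c(Xyl_max = "daily_max", Xyl_mean = "daily_mean",
                    Xyl_min = "daily_min"),
                  function(resp) stepwise_regression(sdat[[resp]], pool,
                                                     alpha_in, alpha_out))

  amp_fit <- fit_log_amplitude(sdat$amplitude, sdat$vpd_max)
  amp_cors <- lapply(c("vpd_max", "sr_mean", "t_max", "rh_min", "p_sum",
                       "swc_mean"),
                     function(v) {
                       s <- spearman_cor(sdat$amplitude, sdat[[v]])
                       data.frame(predictor = v, rho = s$rho, p = s$p, n = s$n)
                     })
  amp_cors <- do.call(rbind, amp_cors)

  win <- longest_complete_window(xylem$radius, innerbark$radius)
  lag <- if (length(win) >= 3L * STEPS_PER_DAY) {
    estimate_lag(xylem$radius[win], innerbark$radius[win],
                 xylem$timestamp[win], max_lag_hours)
  } else NA_real_

  ar <- amplitude_ratio(d_ib, d_xyl, season_only = season_only)

  out <- list(residual_coupling = rc,
              correlation_matrix = ctab,
              stepwise_models = steps,
              amplitude_fits = list(log_fit = amp_fit, spearman = amp_cors),
              lag_hours = lag,
              amplitude_ratio = ar,
              daily_xylem = d_xyl, daily_innerbark = d_ib,
              daily_climate = d_clim,
              residuals = list(xylem = res_x, innerbark = res_b))
  class(out) <- "coupling_report"
  out
}

#' @export
print.coupling_report <- function(x, ...) {
  cat(sprintf(paste0("<coupling_report>\n",
                     "  residual coupling: rho = %.3f (p = %.3g, n = %d)\n",
                     "  inner-bark lag behind xylem: %.2f h\n",
                     "  bark:xylem amplitude ratio: %.2f\n",
                     "  amplitude ~ ln(VPDmax): R^2 = %.3f (linear %.3f)\n"),
              x$residual_coupling$rho, x$residual_coupling$p,
              x$residual_coupling$n, x$lag_hours, x$amplitude_ratio$ratio,
              x$amplitude_fits$log_fit$r_squared,
              x$amplitude_fits$log_fit$r_squared_linear))
  invisible(x)
}

#' Default run configuration
#'
#' @param out_dir output directory for the bundle.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param simulate simulation block (`weather`, `hydraulics`, `n_trees`)
#'   or `NULL` when reading CSVs.
#' @param input list with `dendro_csv` and `climate_csv` paths (and optional
#'   `col_map`), or `NULL` when simulating.
#' @param preprocess,metrics,detrend,stats stage-option lists; see
#'   [run_pipeline()].
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = list(), input = NULL,
                       preprocess = list(), metrics = list(), detrend = list(),
                       stats = list(), log_level = "info") {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
              input = input, preprocess = preprocess, metrics = metrics,
              detrend = detrend, stats = stats, log_level = log_level)
  has_sim <- length(cfg$simulate) > 0 || is.null(cfg$input)
  if (!is.null(cfg$input) && length(cfg$simulate) > 0) {
    stopf("configuration error: exactly one of 'input' and 'simulate' may be given")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file; keys mirror the [run_config()] arguments.
#' @param overrides named list merged over the file (e.g. seed, out_dir).
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  for (nm in names(overrides)) raw[[nm]] <- overrides[[nm]]
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

plog <- function(cfg, fmt, ...) {
  if (!identical(cfg$log_level, "quiet")) message(sprintf(fmt, ...))
}

#' Run the full pipeline and write the output bundle
#'
#' Stages: obtain data (simulate a stand, or read dendrometer + climate
#' CSVs), preprocess (thermal correction unless `preprocess$skip_thermal`,
#' inner-bark decomposition, tree aggregation), daily metrics, detrending,
#' coupling statistics. Writes `climate.csv`, `dendro.csv`,
#' `daily_radius.csv`, `daily_climate.csv`, `table1.csv`, `residuals.csv`,
#' `table2.csv`, `table3.csv`, `fig6_fits.csv`, `coupling_report.json`,
#' `truth.json` (simulation only) and `manifest.json` into `out_dir`.
#' Identical configurations (including seed) produce byte-identical bundles.
#'
#' @param config a [run_config()], or a path to a YAML file.
#' @param overrides named list merged over a YAML config.
#' @return Invisibly, a list with the coupling report, the manifest and the
#'   output directory.
#' @export
run_pipeline <- function(config, overrides = list()) {
  if (is.character(config)) config <- read_run_config(config, overrides)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  # --- stage: data ----------------------------------------------------------
  simulated <- is.null(cfg$input)
  if (simulated) {
    seeds <- derive_seeds(cfg$seed, 2L)
    wargs <- cfg$simulate$weather %||% list()
    wargs$seed <- wargs$seed %||% seeds[1L]
    climate <- generate_weather(do.call(weather_config, wargs))
    hargs <- cfg$simulate$hydraulics %||% list()
    hargs$seed <- hargs$seed %||% seeds[2L]
    params <- do.call(hydraulic_params, hargs)
    n_trees <- cfg$simulate$n_trees %||% 4L
    plog(cfg, "simulate: %d days, %d trees", nrow(climate) / 48L, n_trees)
    stand <- simulate_stand(climate, params, n_trees)
    raw <- list()
    for (nm in names(stand)) {
      raw[[paste0(nm, ".overbark")]] <- stand[[nm]]$overbark
      raw[[paste0(nm, ".xylem")]] <- stand[[nm]]$xylem
    }
    truth_summary <- lapply(stand, function(s) {
      st <- s$truth$states
      list(psi_x_min = min(st$psi_x), psi_s_min = min(st$psi_s),
           growth_um = max(st$growth), turnover = sum(abs(st$q)) * DT_HOURS)
    })
    jsonlite::write_json(list(params = unclass(params), trees = truth_summary),
                         file.path(cfg$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    plog(cfg, "ingest: %s + %s", cfg$input$dendro_csv, cfg$input$climate_csv)
    raw <- read_dendro_csv(cfg$input$dendro_csv, cfg$input$col_map,
                           corrected = isTRUE(cfg$input$corrected))
    climate <- read_climate_csv(cfg$input$climate_csv, cfg$input$col_map)
  }
  write_climate_csv(climate, file.path(cfg$out_dir, "climate.csv"))
  write_dendro_csv(raw, file.path(cfg$out_dir, "dendro.csv"))
  counts$climate_records <- nrow(climate)

  # --- stage: preprocess ----------------------------------------------------
  pcfg <- preprocess_config(
    coeff_bark = cfg$preprocess$coeff_bark %||% 0.2,
    coeff_xylem = cfg$preprocess$coeff_xylem %||% 1.08)
  skip_thermal <- isTRUE(cfg$preprocess$skip_thermal)
  positions <- vapply(raw, function(tr) attr(tr, "position"), "")
  trees <- unique(vapply(raw, function(tr) attr(tr, "tree_id"), ""))
  per_tree <- lapply(trees, function(id) {
    grab <- function(pos) {
      i <- which(positions == pos &
                   vapply(raw, function(tr) attr(tr, "tree_id"), "") == id)
      if (!length(i)) stopf("tree '%s' has no %s trace", id, pos)
      raw[[i[1L]]]
    }
    ob <- grab("overbark"); xy <- grab("xylem")
    if (!skip_thermal && !attr(ob, "corrected")) {
      ob <- thermal_correct(ob, climate, pcfg)
      xy <- thermal_correct(xy, climate, pcfg)
    } else {
      attr(ob, "corrected") <- TRUE
      attr(xy, "corrected") <- TRUE
    }
    list(xylem = xy, innerbark = decompose_inner_bark(ob, xy))
  })
  names(per_tree) <- trees
  mean_xyl <- aggregate_as_trace(
    aggregate_trees(lapply(per_tree, `[[`, "xylem")), "mean")
  mean_ib <- aggregate_as_trace(
    aggregate_trees(lapply(per_tree, `[[`, "innerbark")), "mean")
  plog(cfg, "preprocess: %d trees corrected and decomposed", length(trees))

  # --- stage: daily + detrend + coupling ------------------------------------
  min_cov <- cfg$metrics$min_coverage %||% 0.9
  cutoffs <- cfg$detrend$cutoff_days %||% c(10, 25)
  rep_out <- coupling_report(
    mean_xyl, mean_ib, climate,
    cutoff_days = cutoffs[1L], min_coverage = min_cov,
    alpha_in = cfg$stats$alpha_in %||% 0.05,
    alpha_out = cfg$stats$alpha_out %||% 0.10,
    max_lag_hours = cfg$stats$max_lag_hours %||% 12)

  d_all <- rbind(rep_out$daily_xylem, rep_out$daily_innerbark)
  utils::write.csv(d_all, file.path(cfg$out_dir, "daily_radius.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(rep_out$daily_climate,
                   file.path(cfg$out_dir, "daily_climate.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(growing_season_summary(rep_out$daily_climate),
                   file.path(cfg$out_dir, "table1.csv"),
                   row.names = FALSE, na = "")

  res_rows <- list()
  for (cd in cutoffs) {
    for (pos in c("xylem", "innerbark")) {
      dtab <- rep_out[[paste0("daily_", pos)]]
      full <- data.frame(date = seq(min(dtab$date), max(dtab$date), by = 1L))
      dtab <- merge(full, dtab[, c("date", "daily_mean")], by = "date", all.x = TRUE)
      rs <- residualize(dtab$daily_mean, cd, dtab$date)
      res_rows[[paste(cd, pos)]] <- data.frame(
        date = rs$date, position = pos, original_um = rs$original,
        smooth_um = rs$smooth, residual_um = rs$residual, cutoff_days = cd)
    }
  }
  utils::write.csv(do.call(rbind, res_rows),
                   file.path(cfg$out_dir, "residuals.csv"),
                   row.names = FALSE, na = "")

  utils::write.csv(rep_out$correlation_matrix,
                   file.path(cfg$out_dir, "table2.csv"),
                   row.names = FALSE, na = "")
  t3 <- do.call(rbind, lapply(names(rep_out$stepwise_models), function(nm) {
    m <- rep_out$stepwise_models[[nm]]
    data.frame(response = nm, m$coefficients,
               adj_r_squared = m$adj_r_squared, f_value = m$f_value,
               df1 = m$df[1L], df2 = m$df[2L], n = m$n)
  }))
  utils::write.csv(t3, file.path(cfg$out_dir, "table3.csv"),
                   row.names = FALSE, na = "")
  f6 <- rep_out$amplitude_fits
  utils::write.csv(cbind(f6$spearman,
                         log_a = f6$log_fit$a, log_b = f6$log_fit$b,
                         log_r_squared = f6$log_fit$r_squared,
                         linear_r_squared = f6$log_fit$r_squared_linear),
                   file.path(cfg$out_dir, "fig6_fits.csv"),
                   row.names = FALSE, na = "")

  report_json <- list(
    residual_coupling = rep_out$residual_coupling,
    lag_hours = rep_out$lag_hours,
    amplitude_ratio = rep_out$amplitude_ratio,
    log_fit = rep_out$amplitude_fits$log_fit,
    stepwise = lapply(rep_out$stepwise_models, function(m) {
      list(selected = m$selected, adj_r_squared = m$adj_r_squared,
           f_value = m$f_value, df = m$df, n = m$n,
           coefficients = m$coefficients)
    }))
  jsonlite::write_json(report_json, file.path(cfg$out_dir, "coupling_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  counts$daily_days_total <- length(unique(d_all$date))
  counts$daily_days_valid_xylem <- sum(!is.na(rep_out$daily_xylem$daily_mean))
  counts$daily_days_dropped_xylem <-
    counts$daily_days_total - counts$daily_days_valid_xylem
  plog(cfg, "daily: %d days (%d valid for xylem)", counts$daily_days_total,
       counts$daily_days_valid_xylem)

  manifest <- list(package = "stemflux",
                   version = as.character(utils::packageVersion("stemflux")),
                   seed = cfg$seed,
                   config = unclass(cfg)[c("simulate", "input", "preprocess",
                                           "metrics", "detrend", "stats")],
                   row_counts = counts)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  plog(cfg, "done: bundle written to %s", cfg$out_dir)
  invisible(list(report = rep_out, manifest = manifest, out_dir = cfg$out_dir))
}
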