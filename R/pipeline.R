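# End-to-end pipeline: simulate (or ingest) -> extract frequencies of
# interest -> segment & average over usable runs -> diagnose under the
# control configurations -> bootstrap ROC evaluation -> report.

#' Pipeline configuration
#'
#' Gathers every numeric constant of the method in one serialisable object:
#' the 15% second-peak retention threshold, the 5% height trim, the 2 Hz /
#' 10% run-irregularity rule, the usable 20--23 Hz actuation band, the
#' tolerance and sweep grid, the configuration presets, and the bootstrap
#' sizes (50 draws, 200 trials).
#'
#' @param seed Master seed; every random stage derives its seed from it.
#' @param n_healthy,n_cancerous,input_frequencies,n_points,sampling_rate,duration,noise_sd,boundary_noise_gain,stiffness_range,tumor_extent
#'   Cohort-simulation settings (see [synth_cohort()]); ignored when
#'   `input_dir` points at recorded bundles.
#' @param input_dir Optional directory of recording bundles plus
#'   `manifest.csv`; when given, ingestion replaces simulation.
#' @param magnitude_threshold,trim_fraction,irregular_hz,max_irregular_fraction,band,match_tolerance,exclusion_halfwidth
#'   Extraction/selection thresholds.
#' @param tolerance Diagnostic tolerance (default 0.34, the published
#'   optimum for its configuration).
#' @param tolerance_grid Sweep grid for ROC evaluation.
#' @param configurations List of [configuration()]s (default presets).
#' @param diagnose_configs Configuration ids diagnosed at `tolerance`.
#' @param combine Combination rule across `diagnose_configs` (`"or"` or
#'   `"none"`).
#' @param evaluate_configs Configuration ids given full bootstrap ROC fits.
#' @param n_draw,n_trials Bootstrap resample size and count.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_healthy = 13, n_cancerous = 13,
                            input_frequencies = 20:23,
                            n_points = 1000, sampling_rate = 500,
                            duration = 1, noise_sd = 0.02,
                            boundary_noise_gain = 3,
                            stiffness_range = c(4, 10),
                            tumor_extent = "table1",
                            input_dir = NULL,
                            magnitude_threshold = 0.15,
                            trim_fraction = 0.05,
                            irregular_hz = 2,
                            max_irregular_fraction = 0.10,
                            band = c(20, 23),
                            match_tolerance = NULL,
                            exclusion_halfwidth = 2,
                            tolerance = 0.34,
                            tolerance_grid = seq(0, 1, by = 0.05),
                            configurations = preset_configurations(),
                            diagnose_configs = c(1, 3),
                            combine = "or",
                            evaluate_configs = 1:12,
                            n_draw = 50, n_trials = 200) {
  check_number(magnitude_threshold, "magnitude_threshold", 0, 1)
  check_number(trim_fraction, "trim_fraction", 0, 0.5, strict_upper = TRUE)
  check_number(irregular_hz, "irregular_hz", lower = 0)
  check_number(max_irregular_fraction, "max_irregular_fraction", 0, 1)
  check_number(tolerance, "tolerance", lower = 0)
  if (!combine %in% c("or", "none"))
    stop_invalid('`combine` must be "or" or "none"')
  structure(
    list(seed = as.integer(seed),
         n_healthy = as.numeric(n_healthy),
         n_cancerous = as.numeric(n_cancerous),
         input_frequencies = as.numeric(input_frequencies),
         n_points = as.numeric(n_points),
         sampling_rate = as.numeric(sampling_rate),
         duration = as.numeric(duration), noise_sd = as.numeric(noise_sd),
         boundary_noise_gain = as.numeric(boundary_noise_gain),
         stiffness_range = as.numeric(stiffness_range),
         tumor_extent = tumor_extent,
         input_dir = input_dir,
         magnitude_threshold = as.numeric(magnitude_threshold),
         trim_fraction = as.numeric(trim_fraction),
         irregular_hz = as.numeric(irregular_hz),
         max_irregular_fraction = as.numeric(max_irregular_fraction),
         band = as.numeric(band),
         match_tolerance = if (is.null(match_tolerance)) NULL else
           as.numeric(match_tolerance),
         exclusion_halfwidth = as.numeric(exclusion_halfwidth),
         tolerance = as.numeric(tolerance),
         tolerance_grid = as.numeric(tolerance_grid),
         configurations = configurations,
         diagnose_configs = as.numeric(diagnose_configs),
         combine = combine,
         evaluate_configs = as.numeric(evaluate_configs),
         n_draw = as.numeric(n_draw), n_trials = as.numeric(n_trials)),
    class = "pipeline_config"
  )
}

#' Serialise / restore a pipeline configuration
#'
#' JSON round trip; `read_pipeline_config(write_pipeline_config(cfg, p))`
#' reproduces `cfg` exactly.
#'
#' @param config A [pipeline_config()].
#' @param path JSON path.
#' @return `path` invisibly; the reader returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$configurations <- lapply(x$configurations, function(cf)
    list(id = cf$id, control = cf$control_map))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cfgs <- lapply(x$configurations, function(cf)
    configuration(cf$id, unlist(cf$control)))
  x$configurations <- NULL
  args <- x[!vapply(x, is.null, TRUE)]
  do.call(pipeline_config, c(args, list(configurations = cfgs)))
}

#' Averaged segment tables for a cohort of recordings
#'
#' Groups recordings by breast, keeps runs inside the usable actuation band,
#' extracts frequencies of interest, trims the height fringes, assigns
#' segments, drops runs with too many irregular segments and averages the
#' per-run tables. This is the shared front half of the pipeline.
#'
#' @param recordings List of `surface_motion_recording`s (all runs, all
#'   breasts).
#' @param band Usable actuation band `c(low, high)` Hz, inclusive.
#' @param trim_fraction,magnitude_threshold,match_tolerance,exclusion_halfwidth,irregular_hz,max_irregular_fraction
#'   Thresholds as in the stage functions.
#' @return List with `tables` (named list of averaged `segment_table`s),
#'   `run_selection` (per breast-run retention diagnostics) and `counts`
#'   (exclusion bookkeeping: trimmed points, points dropped by the 15% rule,
#'   degenerate points, rejected runs).
#' @export
cohort_segment_tables <- function(recordings, band = c(20, 23),
                                  trim_fraction = 0.05,
                                  magnitude_threshold = 0.15,
                                  match_tolerance = NULL,
                                  exclusion_halfwidth = 2,
                                  irregular_hz = 2,
                                  max_irregular_fraction = 0.10) {
  freqs <- vapply(recordings, `[[`, numeric(1), "input_frequency")
  in_band <- freqs >= band[1] & freqs <= band[2]
  if (!any(in_band))
    stop_dietdx(sprintf(
      "no runs inside the usable band %g-%g Hz (runs at: %s)",
      band[1], band[2], paste(sort(unique(freqs)), collapse = ", ")),
      "dietdx_empty_selection")
  recordings <- recordings[in_band]
  ids <- vapply(recordings, `[[`, character(1), "breast_id")

  tables <- list()
  sel_rows <- list()
  counts <- list(n_trimmed = 0L, n_low_second = 0L, n_degenerate = 0L,
                 n_rejected_runs = 0L)
  for (bid in unique(ids)) {
    runs <- recordings[ids == bid]
    run_tables <- list()
    dom_means <- list()
    f_in <- numeric(0)
    for (rec in runs) {
      foi <- extract_foi(rec, magnitude_threshold = magnitude_threshold,
                         match_tolerance = match_tolerance,
                         exclusion_halfwidth = exclusion_halfwidth)
      keep <- trim_by_height(rec$points, trim_fraction)
      counts$n_trimmed <- counts$n_trimmed + (nrow(rec$points) - length(keep))
      trimmed <- rec$points[rec$points$point_id %in% keep, , drop = FALSE]
      asg <- assign_segments(trimmed, rec$side)
      foi_kept <- foi[foi$point_id %in% keep, , drop = FALSE]
      counts$n_low_second <- counts$n_low_second +
        sum(foi_kept$reason %in% "low_second")
      counts$n_degenerate <- counts$n_degenerate +
        sum(foi_kept$reason %in% "degenerate")
      run_tables[[length(run_tables) + 1]] <-
        segment_table(foi, asg, breast_id = bid,
                      run_hz = rec$input_frequency)
      dom_means[[length(dom_means) + 1]] <- dominant_segment_means(foi, asg)
      f_in <- c(f_in, rec$input_frequency)
    }
    sel <- select_usable_runs(dom_means, f_in, irregular_hz = irregular_hz,
                              max_irregular_fraction = max_irregular_fraction)
    counts$n_rejected_runs <- counts$n_rejected_runs + sum(!sel$retained)
    sel$breast_id <- bid
    sel_rows[[length(sel_rows) + 1]] <- sel
    tables[[bid]] <- average_tables(run_tables[sel$retained])
  }
  list(tables = tables, run_selection = do.call(rbind, sel_rows),
       counts = counts)
}

#' Run the full pipeline
#'
#' Simulate (or ingest) -> extract -> segment -> diagnose -> evaluate ->
#' report. Every stage's artifact lands under `out_dir` when given:
#' `manifest.csv`, `segments.csv`, `diagnosis.csv`, `roc_points.csv`,
#' `fits.csv`, `report.md` and `counts.json`. Rerunning with the same
#' configuration reproduces every artifact byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return Invisibly, a list with the manifest, averaged tables, calls,
#'   per-configuration fits, the best configuration's criteria report and
#'   the bookkeeping counts.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_dietdx(sprintf("[stage %s] %s", name, conditionMessage(e)),
                  "dietdx_stage_error"))
  }

  sim <- stage("simulate", {
    if (!is.null(config$input_dir)) {
      dirs <- list.dirs(config$input_dir, recursive = FALSE)
      list(recordings = lapply(dirs, read_recording_bundle),
           manifest = read_manifest(file.path(config$input_dir,
                                              "manifest.csv")))
    } else {
      synth_cohort(
        n_healthy = config$n_healthy, n_cancerous = config$n_cancerous,
        input_frequencies = config$input_frequencies, seed = config$seed,
        stiffness_range = config$stiffness_range,
        tumor_extent = config$tumor_extent,
        n_points = config$n_points, sampling_rate = config$sampling_rate,
        duration = config$duration, noise_sd = config$noise_sd,
        boundary_noise_gain = config$boundary_noise_gain)
    }
  })
  labels <- sim$manifest[c("breast_id", "label")]

  seg <- stage("segment", cohort_segment_tables(
    sim$recordings, band = config$band,
    trim_fraction = config$trim_fraction,
    magnitude_threshold = config$magnitude_threshold,
    match_tolerance = config$match_tolerance,
    exclusion_halfwidth = config$exclusion_halfwidth,
    irregular_hz = config$irregular_hz,
    max_irregular_fraction = config$max_irregular_fraction))

  cfg_by_id <- function(id) {
    ids <- vapply(config$configurations, `[[`, integer(1), "id")
    config$configurations[[match(id, ids)]]
  }

  calls <- stage("diagnose", {
    rows <- lapply(names(seg$tables), function(bid) {
      outs <- lapply(config$diagnose_configs, function(cid)
        diagnose(seg$tables[[bid]], cfg_by_id(cid), config$tolerance,
                 on_indeterminate = "na"))
      per <- vapply(outs, `[[`, logical(1), "is_positive")
      row <- data.frame(breast_id = bid)
      for (k in seq_along(config$diagnose_configs))
        row[[sprintf("config_%d", config$diagnose_configs[k])]] <- per[k]
      row$positive <- if (config$combine == "or") combine_or(per) else per[1]
      row
    })
    do.call(rbind, rows)
  })

  eval_res <- stage("evaluate", {
    fits <- list(); roc_points <- list()
    for (cid in config$evaluate_configs) {
      bp <- bootstrap_points(seg$tables, labels, cfg_by_id(cid),
                             n_draw = config$n_draw,
                             n_trials = config$n_trials,
                             grid = config$tolerance_grid,
                             seed = child_seed(config$seed, 7000L + cid))
      fit <- fit_exponential_roc(bp, configuration_id = cid)
      op <- operating_points(fit$a)
      fits[[length(fits) + 1]] <- data.frame(
        configuration = cid, a = fit$a, auc = fit$auc,
        optimal_sensitivity = op$optimal$sensitivity_pct,
        optimal_specificity = op$optimal$specificity_pct,
        sens_at_spec80 = op$at_specificity_80$sensitivity_pct,
        spec_at_sens80 = op$at_sensitivity_80$specificity_pct)
      bp$configuration <- cid
      roc_points[[length(roc_points) + 1]] <- bp
    }
    list(fits = do.call(rbind, fits),
         roc_points = do.call(rbind, roc_points))
  })
  best <- eval_res$fits[which.max(eval_res$fits$auc), ]
  best_report <- criteria_report(structure(
    list(a = best$a, auc = best$auc, n_points = NA,
         configuration = best$configuration), class = "bootstrap_fit"))

  conf <- confusion(calls[c("breast_id", "positive")], labels)
  counts <- c(seg$counts, list(
    n_indeterminate_breasts = sum(is.na(calls$positive)),
    sensitivity_at_tolerance = conf$sensitivity,
    specificity_at_tolerance = conf$specificity))

  result <- list(manifest = sim$manifest, tables = seg$tables,
                 run_selection = seg$run_selection, calls = calls,
                 fits = eval_res$fits, roc_points = eval_res$roc_points,
                 best_configuration = best$configuration,
                 criteria = best_report, counts = counts)

  if (!is.null(out_dir)) stage("report", {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_manifest(sim$manifest, file.path(out_dir, "manifest.csv"))
    segs <- do.call(rbind, lapply(result$tables, function(tb) {
      g <- expand.grid(radial = 0:3, zband = 0:3)
      data.frame(breast_id = tb$breast_id, g,
                 mean_foi_hz = as.vector(tb$mean_foi),
                 count = as.vector(tb$counts))
    }))
    write.csv(segs, file.path(out_dir, "segments.csv"), row.names = FALSE)
    write.csv(calls, file.path(out_dir, "diagnosis.csv"), row.names = FALSE)
    write.csv(eval_res$roc_points, file.path(out_dir, "roc_points.csv"),
              row.names = FALSE)
    write.csv(eval_res$fits, file.path(out_dir, "fits.csv"),
              row.names = FALSE)
    jsonlite::write_json(counts, file.path(out_dir, "counts.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(render_report(result), file.path(out_dir, "report.md"))
  })
  invisible(result)
}

# Per-configuration summary in the layout of the published AUC table.
render_report <- function(result) {
  f <- result$fits
  lines <- c(
    "# Diagnostic evaluation report", "",
    sprintf("Cohort: %d breasts (%d cancerous, %d healthy).",
            nrow(result$manifest),
            sum(result$manifest$label == "cancerous"),
            sum(result$manifest$label == "healthy")),
    sprintf("Best configuration: %d (AUC %.2f).",
            result$best_configuration, max(f$auc)), "",
    paste(c("| |", sprintf("C%d |", f$configuration)), collapse = " "),
    paste0(paste(rep("|---", nrow(f) + 1), collapse = ""), "|"),
    paste(c("| AUC |", sprintf("%.2f |", f$auc)), collapse = " "),
    paste(c("| Optimal sensitivity |",
            sprintf("%d |", f$optimal_sensitivity)), collapse = " "),
    paste(c("| Optimal specificity |",
            sprintf("%d |", f$optimal_specificity)), collapse = " "),
    paste(c("| Sensitivity (80% specificity) |",
            sprintf("%d |", f$sens_at_spec80)), collapse = " "),
    paste(c("| Specificity (80% sensitivity) |",
            sprintf("%d |", f$spec_at_sens80)), collapse = " "),
    "",
    sprintf("At the working tolerance: sensitivity %s, specificity %s.",
            format(result$counts$sensitivity_at_tolerance, digits = 3),
            format(result$counts$specificity_at_tolerance, digits = 3))
  )
  lines
}
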