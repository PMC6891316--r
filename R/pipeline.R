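#' Analyze one EEG epoch
#'
#' Runs the full per-epoch chain: resample to the analysis working rate,
#' wavelet-packet decomposition, theta-band reconstruction and channel
#' correlation matrix, network metrics at a fixed threshold (optional),
#' spectral fatigue ratio, and eye-movement detection on the raw F3/F4 pair.
#'
#' @param rec An \code{eeg_recording}.
#' @param T Network threshold in (0,1), or NA to skip network metrics.
#' @param working_fs Analysis working rate (default 128 Hz).
#' @param level,wavelet Wavelet-packet settings (see
#'   \code{\link{wpd_decompose}}).
#' @param ratio_channels Channel subset for the fatigue ratio.
#' @param det_params \code{\link{detector_params}} for the eye detector.
#' @return List: \code{corr} (theta-band \code{corr_matrix}),
#'   \code{metrics} (or NULL), \code{ratio} (\code{power_ratio_result}),
#'   \code{events}, \code{eye_rate}, \code{duration}.
#' @export
analyze_epoch <- function(rec, T = NA, working_fs = 128, level = 4L,
                          wavelet = "db16", ratio_channels = c("P3", "P4"),
                          det_params = detector_params()) {
  events <- detect_events(rec, det_params)
  work <- resample_recording(rec, working_fs)
  bs <- wpd_decompose(work, level = level, wavelet = wavelet)
  theta <- extract_band(bs, "theta")
  corr <- correlation_matrix(theta)
  metrics <- if (!is.na(T)) network_metrics(build_adjacency(corr, T)) else NULL
  ratio <- power_ratio(bs, ratio_channels)
  dur <- recording_duration(rec)
  list(corr = corr, metrics = metrics, ratio = ratio, events = events,
       eye_rate = eye_rate(events, dur), duration = dur)
}

# Resolve an epoch source: in-memory sim_study, regenerable sim_study, or a
# directory of CSV epochs keyed "S<subject>_<condition>_<stage>.csv".
.epoch_getter <- function(study) {
  if (inherits(study, "sim_study")) {
    if (!is.null(study$epochs)) {
      function(subject, condition, stage) {
        key <- sprintf("S%02d_%s_%d", subject, condition, stage)
        study$epochs[[key]]$recording
      }
    } else {
      function(subject, condition, stage)
        simulate_epoch(study$config, subject, condition, stage)$recording
    }
  } else if (is.character(study) && dir.exists(study)) {
    function(subject, condition, stage) {
      path <- file.path(study, sprintf("S%02d_%s_%d.csv", subject,
                                       condition, stage))
      if (!file.exists(path)) stop("missing epoch file: ", path,
                                   call. = FALSE)
      read_recording(path)
    }
  } else stop("study must be a sim_study or an epoch directory",
              call. = FALSE)
}

.study_meta <- function(study) {
  if (inherits(study, "sim_study")) return(study$meta)
  meta_path <- file.path(study, "study_meta.csv")
  if (!file.exists(meta_path)) {
    files <- list.files(study, pattern = "^S[0-9]+_(normal|mrm)_[0-9]+\\.csv$")
    if (!length(files)) stop("no recordings found in ", study, call. = FALSE)
    parts <- regmatches(files,
                        regexec("^S([0-9]+)_(normal|mrm)_([0-9]+)\\.csv$",
                                files))
    return(data.frame(
      subject = as.integer(vapply(parts, `[`, "", 2)),
      condition = vapply(parts, `[`, "", 3),
      stage = as.integer(vapply(parts, `[`, "", 4)),
      sq_score = NA_integer_, n_trials = NA_integer_,
      n_errors = NA_integer_, stringsAsFactors = FALSE))
  }
  utils::read.csv(meta_path, stringsAsFactors = FALSE)
}

#' Analyze a full driving study
#'
#' The end-to-end pipeline: per-epoch band decomposition, theta-band
#' correlation networks, spectral fatigue ratios and eye-movement rates are
#' aggregated into a study table; the network threshold is either fixed or
#' selected by the significance sweep; per-condition stage trends and
#' between-condition comparisons are tested.
#'
#' @param study A \code{sim_study} (from \code{\link{simulate_study}}) or a
#'   directory of epoch CSVs written by it.
#' @param threshold Fixed network threshold, or \code{"sweep"} (default) to
#'   select it by the stage-contrast significance sweep on the normal-mode
#'   epochs.
#' @param sweep_grid Threshold grid for the sweep.
#' @param alpha Significance level used in the sweep and the group tests.
#' @param working_fs,level,wavelet,ratio_channels,det_params Per-epoch
#'   analysis settings (see \code{\link{analyze_epoch}}).
#' @param stats_design t-test design for sweep and condition comparisons.
#' @return A \code{fatigue_study} object: \code{table} (a
#'   \code{\link{study_table}}), \code{sweep} (a \code{threshold_sweep} or
#'   NULL), \code{threshold}, \code{report} (data.frame of condition
#'   comparisons), \code{trends}, \code{events} (per-epoch counts),
#'   \code{warnings}.
#' @export
analyze_study <- function(study, threshold = "sweep",
                          sweep_grid = threshold_grid(), alpha = 0.05,
                          working_fs = 128, level = 4L, wavelet = "db16",
                          ratio_channels = c("P3", "P4"),
                          det_params = detector_params(),
                          stats_design = "independent_pooled") {
  if (!inherits(study, "sim_study") &&
      !(is.character(study) && length(study) == 1 && dir.exists(study)))
    stop("study must be a sim_study or an epoch directory", call. = FALSE)
  meta <- .study_meta(study)
  get_rec <- .epoch_getter(study)
  n <- nrow(meta)
  corrs <- vector("list", n)
  ratio <- numeric(n)
  eyer <- numeric(n)
  nev <- integer(n)
  warns <- character(0)
  for (i in seq_len(n)) {
    rec <- get_rec(meta$subject[i], meta$condition[i], meta$stage[i])
    ep <- analyze_epoch(rec, T = NA, working_fs = working_fs, level = level,
                        wavelet = wavelet, ratio_channels = ratio_channels,
                        det_params = det_params)
    corrs[[i]] <- ep$corr
    ratio[i] <- ep$ratio$selected
    if (length(ep$ratio$undefined_channels))
      warns <- c(warns, sprintf(
        "epoch %d: undefined ratio on %s", i,
        paste(ep$ratio$undefined_channels, collapse = ",")))
    eyer[i] <- ep$eye_rate
    nev[i] <- nrow(ep$events)
  }

  sweep <- NULL
  if (identical(threshold, "sweep")) {
    normal_idx <- which(meta$condition == "normal")
    samples <- sweep_metric_samples(corrs[normal_idx],
                                    meta[normal_idx, , drop = FALSE],
                                    grid = sweep_grid)
    sweep <- sweep_threshold(samples, grid = sweep_grid, alpha = alpha,
                             design = stats_design)
    threshold <- sweep$selected_T
    if (is.na(threshold)) {
      warns <- c(warns,
                 "threshold sweep found no significant interval; falling back to grid midpoint")
      threshold <- stats::median(sweep_grid)
    }
  }
  C <- numeric(n); G <- numeric(n)
  for (i in seq_len(n)) {
    m <- network_metrics(build_adjacency(corrs[[i]], threshold))
    C[i] <- m$C; G[i] <- m$G
  }

  err <- if (all(c("n_errors", "n_trials") %in% names(meta)))
    ifelse(!is.na(meta$n_trials) & meta$n_trials > 0,
           meta$n_errors / meta$n_trials, NA_real_) else NA_real_
  tab <- study_table(data.frame(
    subject = sprintf("S%02d", meta$subject), condition = meta$condition,
    stage = meta$stage, C = C, G = G, power_ratio = ratio, eye_rate = eyer,
    sq_score = if ("sq_score" %in% names(meta)) meta$sq_score else NA,
    error_rate = err, stringsAsFactors = FALSE))

  conds <- intersect(c("normal", "mrm"), unique(tab$condition))
  cols <- c("C", "G", "power_ratio", "eye_rate", "sq_score")
  trends <- list()
  for (cond in conds)
    for (col in cols)
      trends[[paste(cond, col, sep = ".")]] <-
        stage_trend(tab, col, cond)
  report <- NULL
  if (length(conds) == 2) {
    rows <- lapply(cols, function(col) {
      cc <- compare_conditions(tab, col, design = stats_design,
                               alpha = alpha)
      data.frame(column = col, t = cc$test$t, df = cc$test$df,
                 p = cc$test$p, t_crit = cc$test$t_crit,
                 significant = cc$test$significant,
                 stringsAsFactors = FALSE)
    })
    report <- do.call(rbind, rows)
  }
  structure(list(table = tab, sweep = sweep, threshold = threshold,
                 report = report, trends = trends,
                 events = data.frame(subject = meta$subject,
                                     condition = meta$condition,
                                     stage = meta$stage, n_events = nev),
                 warnings = warns, alpha = alpha),
            class = "fatigue_study")
}

#' @export
print.fatigue_study <- function(x, ...) {
  cat(sprintf("Driving-fatigue study analysis: %d epochs, network threshold T = %.4f%s\n",
              nrow(x$table), x$threshold,
              if (!is.null(x$sweep)) " (sweep-selected)" else ""))
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "(see $warnings)\n")
  invisible(x)
}

#' @export
summary.fatigue_study <- function(object, ...) {
  x <- object
  print(x)
  cat("\nStage trends (Spearman rho of stage vs per-stage mean):\n")
  for (nm in names(x$trends))
    cat(sprintf("  %-22s rho = %+.3f\n", nm, x$trends[[nm]]$rho))
  if (!is.null(x$report)) {
    cat(sprintf("\nCondition comparisons (normal vs MRM stage means, alpha = %g):\n",
                x$alpha))
    print(x$report, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
plot.fatigue_study <- function(x, columns = c("C", "G", "power_ratio",
                                              "eye_rate"), ...) {
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (col in columns) {
    stages <- sort(unique(x$table$stage))
    mu <- sapply(intersect(c("normal", "mrm"), unique(x$table$condition)),
                 function(cond) {
                   sub <- x$table[x$table$condition == cond, ]
                   tapply(sub[[col]], sub$stage, mean, na.rm = TRUE)
                 })
    graphics::matplot(stages, mu, type = "b", pch = 16, lty = 1,
                      xlab = "driving stage", ylab = col, main = col, ...)
    graphics::legend("topleft", legend = colnames(mu), col = seq_len(ncol(mu)),
                     pch = 16, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Run the pipeline end to end and archive a run directory
#'
#' Simulates (or loads) a study, analyzes it, and writes the study table,
#' sweep statistics, condition-comparison report, resolved configuration and
#' an md5 manifest of every artifact into \code{out_dir}.
#'
#' @param cfg A \code{\link{sim_config}} (the study is simulated) or a path
#'   to an epoch directory.
#' @param out_dir Output directory (created if needed).
#' @param ... Options passed to \code{\link{analyze_study}}.
#' @return The \code{fatigue_study} object, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg, out_dir, ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), sprintf(...),
                            "\n", sep = "", file = log_path, append = TRUE)
  if (inherits(cfg, "sim_config")) {
    logf("simulating study (seed %d)", cfg$seed)
    study <- simulate_study(cfg, keep_recordings = FALSE)
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    study <- cfg
    logf("loading study from %s", cfg)
  }
  logf("analyzing")
  res <- analyze_study(study, ...)
  write_study_table(res$table, file.path(out_dir, "study_table.csv"))
  if (!is.null(res$sweep))
    utils::write.csv(res$sweep$stat_table,
                     file.path(out_dir, "sweep_stats.csv"), row.names = FALSE)
  if (!is.null(res$report))
    utils::write.csv(res$report, file.path(out_dir, "test_report.csv"),
                     row.names = FALSE)
  jsonlite::write_json(list(threshold = res$threshold,
                            warnings = res$warnings),
                       file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  for (w in res$warnings) logf("warning: %s", w)
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(manifest) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  logf("done")
  invisible(res)
}
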