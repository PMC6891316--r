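#' Configuration for the synthetic driving study
#'
#' Builds the parameter set for a simulated driving-fatigue study shaped like
#' the real design: 12 subjects, two driving conditions (normal and MRM, the
#' man-machine response mode), seven half-hourly stages, one multichannel EEG
#' epoch per cell.  Fatigue is emulated by per-stage schedules: theta/alpha
#' power rises and beta power falls with stage, inter-channel theta coupling
#' rises, the lateral eye-movement rate falls, subjective fatigue (SQ) scores
#' rise, and (MRM only) response error probability rises.  Every MRM schedule
#' drifts at half the normal-mode slope, emulating the intervention's
#' fatigue-slowing effect.
#'
#' Schedules are generated from linear (SQ: piecewise-linear) profiles over
#' stages and can be overridden with explicit per-stage vectors via
#' \code{list(normal = ..., mrm = ...)} arguments.
#'
#' @param n_subjects Number of subjects (default 12).
#' @param stages Number of driving stages (default 7).
#' @param fs Sampling rate in Hz (default 1000; 128 is convenient for fast
#'   simulation since it is the analysis working rate).
#' @param epoch_seconds Epoch duration (default 180, i.e. the 3-minute
#'   collection window).
#' @param seed Integer seed; the full dataset is a deterministic function of
#'   the seed and the configuration.
#' @param band_sd Baseline standard deviations (microvolts) of the theta,
#'   alpha and beta components at multiplier 1.
#' @param band_power_schedule Per-condition lists of per-stage power
#'   multipliers for theta, alpha, beta.
#' @param coupling_schedule Per-condition per-stage target inter-channel
#'   correlation of the theta band, each value in [0, 1).
#' @param eye_rate_schedule Per-condition per-stage expected lateral eye
#'   movements per minute.
#' @param eye_amplitude Deflection amplitude of an ocular event on F3/F4
#'   (microvolts).
#' @param sq_schedule Per-condition per-stage mean SQ score (1-7 scale).
#' @param error_rate_schedule Per-stage response error probability (MRM only).
#' @param n_trials Arithmetic-response trials per MRM stage.
#' @param noise_sd White measurement noise (microvolts).
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(n_subjects = 12L, stages = 7L, fs = 1000,
                       epoch_seconds = 180, seed = 1L,
                       band_sd = c(theta = 6, alpha = 8, beta = 5),
                       band_power_schedule = NULL,
                       coupling_schedule = NULL,
                       eye_rate_schedule = NULL,
                       eye_amplitude = 150,
                       sq_schedule = NULL,
                       error_rate_schedule = NULL,
                       n_trials = 40L,
                       noise_sd = 5) {
  stages <- as.integer(stages)
  if (stages < 1L) stop("stages must be >= 1", call. = FALSE)
  u <- if (stages == 1L) 0 else (seq_len(stages) - 1) / (stages - 1)
  lin <- function(from, to) from + (to - from) * u
  if (is.null(band_power_schedule))
    band_power_schedule <- list(
      normal = list(theta = lin(1, 1.6), alpha = lin(1, 1.48),
                    beta = lin(1, 0.64)),
      mrm = list(theta = lin(1, 1.18), alpha = lin(1, 1.14),
                 beta = lin(1, 0.89)))
  if (is.null(coupling_schedule))
    coupling_schedule <- list(normal = lin(0.25, 0.50), mrm = lin(0.25, 0.325))
  if (is.null(eye_rate_schedule))
    eye_rate_schedule <- list(normal = lin(12, 4), mrm = lin(12, 10.4))
  if (is.null(sq_schedule))
    sq_schedule <- list(
      normal = stats::approx(seq(0, 1, length.out = 7),
                             c(2, 3, 3.5, 4.5, 5.5, 6, 6.5), xout = u)$y,
      mrm = lin(2, 5))
  if (is.null(error_rate_schedule))
    error_rate_schedule <- lin(0.05, 0.2)

  cfg <- list(n_subjects = as.integer(n_subjects), stages = stages, fs = fs,
              epoch_seconds = epoch_seconds, seed = as.integer(seed),
              conditions = c("normal", "mrm"), band_sd = band_sd,
              band_power_schedule = band_power_schedule,
              coupling_schedule = coupling_schedule,
              eye_rate_schedule = eye_rate_schedule,
              eye_amplitude = eye_amplitude, sq_schedule = sq_schedule,
              error_rate_schedule = error_rate_schedule,
              n_trials = as.integer(n_trials), noise_sd = noise_sd)
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  st <- cfg$stages
  chk_len <- function(x, what) {
    if (length(x) != st)
      stop(what, " must have one value per stage (", st, ")", call. = FALSE)
    if (any(!is.finite(x))) stop(what, " has non-finite values", call. = FALSE)
  }
  for (cond in cfg$conditions) {
    for (b in c("theta", "alpha", "beta")) {
      sc <- cfg$band_power_schedule[[cond]][[b]]
      chk_len(sc, paste(cond, b, "power schedule"))
      if (any(sc < 0)) stop("power multipliers must be >= 0", call. = FALSE)
    }
    cc <- cfg$coupling_schedule[[cond]]
    chk_len(cc, paste(cond, "coupling schedule"))
    if (any(cc < 0 | cc >= 1))
      stop("coupling targets must lie in [0, 1)", call. = FALSE)
    er <- cfg$eye_rate_schedule[[cond]]
    chk_len(er, paste(cond, "eye-rate schedule"))
    if (any(er < 0)) stop("eye rates must be >= 0", call. = FALSE)
    chk_len(cfg$sq_schedule[[cond]], paste(cond, "SQ schedule"))
  }
  chk_len(cfg$error_rate_schedule, "error-rate schedule")
  if (any(cfg$error_rate_schedule < 0 | cfg$error_rate_schedule > 1))
    stop("error rates must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulated driving study: %d subjects x 2 conditions x %d stages, %g s epochs @ %g Hz, seed %d\n",
    x$n_subjects, x$stages, x$epoch_seconds, x$fs, x$seed))
  invisible(x)
}

# Deterministic per-epoch seed below 2^31, so each epoch is an independent,
# reproducible substream addressable without generating its predecessors.
.epoch_seed <- function(seed, subject, condition, stage) {
  ci <- match(condition, c("normal", "mrm"))
  as.integer((as.double(seed) * 104729 + subject * 7919 +
                ci * 1299709 + stage * 15485863) %% 2147483629)
}

# Band-limited unit-variance Gaussian noise, synthesized in the frequency
# domain: complex Gaussian spectrum inside [lo, hi), zero outside, inverse
# FFT.  Exactly band-limited and numerically stable at any sampling rate.
.band_noise <- function(n, fs, lo, hi) {
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  inband <- half & freqs >= lo & freqs < hi
  spec <- complex(n)
  k <- which(inband)
  spec[k] <- complex(real = stats::rnorm(length(k)),
                     imaginary = stats::rnorm(length(k)))
  # hermitian symmetry for a real signal
  conj_idx <- n - k + 2L
  ok <- conj_idx >= 1L & conj_idx <= n & conj_idx != k
  spec[conj_idx[ok]] <- Conj(spec[k][ok])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Piecewise-linear ocular deflection: ramp (w samples) - short hold - ramp
# back.  The hold is kept below the detector's default refractory period so
# the onset and offset ramps of one event merge into a single detection.
.eye_shape <- function(w, hold) {
  c(seq(0, 1, length.out = w + 1L)[-1L], rep(1, hold),
    seq(1, 0, length.out = w + 1L)[-1L])
}

#' Simulate one EEG epoch
#'
#' Generates one study epoch: a shared theta-band source mixed into every
#' channel at the scheduled coupling level, independent per-channel
#' theta/alpha/beta band-limited components at the scheduled powers, white
#' measurement noise, and (on F3/F4 only) anti-correlated ramp-and-hold
#' ocular deflections at the scheduled rate.  The injected event list is
#' returned as ground truth.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param subject Subject index (1-based).
#' @param condition \code{"normal"} or \code{"mrm"}.
#' @param stage Stage in \code{1..cfg$stages}.
#' @return A list with elements \code{recording} (an \code{eeg_recording})
#'   and \code{events} (data.frame of ground-truth ocular events:
#'   \code{onset_sample}, \code{offset_sample}, \code{direction}).
#' @export
simulate_epoch <- function(cfg, subject, condition, stage) {
  stopifnot(inherits(cfg, "sim_config"))
  condition <- match.arg(condition, cfg$conditions)
  if (stage < 1L || stage > cfg$stages)
    stop("stage must be in 1..", cfg$stages, call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.epoch_seed(cfg$seed, subject, condition, stage))

  fs <- cfg$fs
  n <- round(fs * cfg$epoch_seconds)
  chans <- study_channels()
  nc <- length(chans)
  defs <- band_definitions()
  mult <- cfg$band_power_schedule[[condition]]
  coup <- cfg$coupling_schedule[[condition]][stage]

  shared_theta <- .band_noise(n, fs, defs$theta[1], defs$theta[2])
  x <- matrix(0, nc, n)
  for (i in seq_len(nc)) {
    th <- sqrt(coup) * shared_theta +
      sqrt(1 - coup) * .band_noise(n, fs, defs$theta[1], defs$theta[2])
    al <- .band_noise(n, fs, defs$alpha[1], defs$alpha[2])
    be <- .band_noise(n, fs, defs$beta[1], defs$beta[2])
    x[i, ] <- cfg$band_sd["theta"] * sqrt(mult$theta[stage]) * th +
      cfg$band_sd["alpha"] * sqrt(mult$alpha[stage]) * al +
      cfg$band_sd["beta"] * sqrt(mult$beta[stage]) * be +
      cfg$noise_sd * stats::rnorm(n)
  }

  # ocular events on F3/F4: opposite-sign deflections, 20-sample ramps
  w <- 20L
  hold <- round(0.1 * fs)
  shape <- .eye_shape(w, hold)
  ev_len <- length(shape)
  rate <- cfg$eye_rate_schedule[[condition]][stage]
  n_ev <- stats::rpois(1, rate * cfg$epoch_seconds / 60)
  onsets <- integer(0)
  min_sep <- ev_len + round(0.5 * fs)
  tries <- 0L
  while (length(onsets) < n_ev && tries < 200L * max(1L, n_ev)) {
    cand <- sample.int(n - ev_len - 1L, 1L)
    if (all(abs(cand - onsets) >= min_sep)) onsets <- c(onsets, cand)
    tries <- tries + 1L
  }
  onsets <- sort(onsets)
  dirs <- sample(c("left", "right"), length(onsets), replace = TRUE)
  f3 <- match("F3", chans); f4 <- match("F4", chans)
  for (k in seq_along(onsets)) {
    idx <- onsets[k] + seq_len(ev_len) - 1L
    sgn <- if (dirs[k] == "right") 1 else -1   # right: F3 deflects positive
    x[f3, idx] <- x[f3, idx] + sgn * cfg$eye_amplitude * shape
    x[f4, idx] <- x[f4, idx] - sgn * cfg$eye_amplitude * shape
  }

  rec <- eeg_recording(x, fs = fs, channel_labels = chans,
                       subject_id = sprintf("S%02d", subject),
                       condition = condition, stage = as.integer(stage))
  events <- data.frame(onset_sample = onsets,
                       offset_sample = onsets + ev_len - 1L,
                       direction = if (length(onsets)) dirs else character(0),
                       stringsAsFactors = FALSE)
  list(recording = rec, events = events)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a full driving study
#'
#' Generates every epoch of the crossed design (subjects x conditions x
#' stages) together with per-cell subjective fatigue scores (rounded draws
#' within one point of the scheduled mean, clipped to 1..7) and, for the MRM
#' condition, binomial response error counts.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param keep_recordings Keep the EEG matrices in memory (default TRUE).
#'   With \code{FALSE} only ground truth, SQ scores and error counts are
#'   returned; epochs can be regenerated on demand with
#'   \code{\link{simulate_epoch}}.
#' @param out_dir Optional directory; when given, each epoch is written as
#'   CSV (plus JSON sidecar) and a \code{study_meta.csv} /
#'   \code{ground_truth.json} pair is written alongside.
#' @return A \code{sim_study} list: \code{config}, \code{epochs} (named list
#'   of \code{simulate_epoch} results, or NULL), \code{meta} (data.frame with
#'   subject, condition, stage, sq_score, error counts and true event count).
#' @export
simulate_study <- function(cfg, keep_recordings = TRUE, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  grid <- expand.grid(stage = seq_len(cfg$stages),
                      condition = cfg$conditions,
                      subject = seq_len(cfg$n_subjects),
                      stringsAsFactors = FALSE)
  epochs <- if (keep_recordings) vector("list", nrow(grid)) else NULL
  meta <- grid[, c("subject", "condition", "stage")]
  meta$sq_score <- NA_integer_
  meta$n_trials <- NA_integer_
  meta$n_errors <- NA_integer_
  meta$true_events <- NA_integer_
  truth <- vector("list", nrow(grid))
  names(truth) <- sprintf("S%02d_%s_%d", grid$subject, grid$condition,
                          grid$stage)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (i in seq_len(nrow(grid))) {
    ep <- simulate_epoch(cfg, grid$subject[i], grid$condition[i],
                         grid$stage[i])
    key <- names(truth)[i]
    truth[[i]] <- ep$events
    meta$true_events[i] <- nrow(ep$events)
    # scalar draws on the same per-epoch substream, after the signal draws
    set.seed(.epoch_seed(cfg$seed + 1L, grid$subject[i],
                         grid$condition[i], grid$stage[i]))
    sq_mean <- cfg$sq_schedule[[grid$condition[i]]][grid$stage[i]]
    sq <- round(sq_mean) + sample(c(-1L, 0L, 1L), 1, prob = c(.25, .5, .25))
    meta$sq_score[i] <- min(7L, max(1L, sq))
    if (grid$condition[i] == "mrm") {
      meta$n_trials[i] <- cfg$n_trials
      meta$n_errors[i] <- stats::rbinom(
        1, cfg$n_trials, cfg$error_rate_schedule[grid$stage[i]])
    }
    if (keep_recordings) epochs[[i]] <- ep
    if (!is.null(out_dir))
      write_recording(ep$recording, file.path(out_dir, paste0(key, ".csv")))
  }
  if (keep_recordings) names(epochs) <- names(truth)
  if (!is.null(out_dir)) {
    utils::write.csv(meta, file.path(out_dir, "study_meta.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         digits = NA)
  }
  structure(list(config = cfg, epochs = epochs, meta = meta,
                 ground_truth = truth),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Simulated study: %d epochs (%d subjects x %d conditions x %d stages)%s\n",
              nrow(x$meta), x$config$n_subjects, length(x$config$conditions),
              x$config$stages,
              if (is.null(x$epochs)) ", recordings not retained" else ""))
  invisible(x)
}
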