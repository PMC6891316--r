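#' Detector parameters for lateral eye movements
#'
#' A lateral eye movement shows as opposite-sign voltage deflections on the
#' symmetric prefrontal channels F3 and F4.  The detector slides a window of
#' \code{window} samples along both channels and fires where the window slope
#' statistic K exceeds \code{k_threshold} (in microvolts per sample) on both
#' channels with opposite signs, and the F3/F4 waveforms over the window are
#' strongly negatively correlated (r < -\code{r_threshold}).
#'
#' @param window Window width in samples (default 20).
#' @param k_threshold Slope threshold, microvolts/sample (default 2).
#' @param r_threshold Absolute correlation gate (default 0.85).
#' @param refractory Merge window in seconds: super-threshold windows closer
#'   than this collapse into one event (default 0.2).
#' @param both_channels Require |K| above threshold on both channels
#'   (default) or on either one.
#' @param f3_positive Direction label assigned when F3 deflects positive
#'   (default \code{"right"}).
#' @return A \code{detector_params} list.
#' @export
detector_params <- function(window = 20L, k_threshold = 2, r_threshold = 0.85,
                            refractory = 0.2, both_channels = TRUE,
                            f3_positive = c("right", "left")) {
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2 samples", call. = FALSE)
  if (k_threshold <= 0 || r_threshold <= 0)
    stop("thresholds must be positive", call. = FALSE)
  structure(list(window = window, k_threshold = k_threshold,
                 r_threshold = r_threshold, refractory = refractory,
                 both_channels = both_channels,
                 f3_positive = match.arg(f3_positive)),
            class = "detector_params")
}

#' Sliding-window slope statistic
#'
#' K_i = (y(x_{i+w}) - y(x_i)) / w for every start index i with i + w in
#' range: the average slope, in microvolts per sample, over a window of w
#' samples.
#'
#' @param signal Numeric vector (one channel).
#' @param window Window width w in samples.
#' @return Numeric vector of length \code{length(signal) - window}.
#' @export
slope_series <- function(signal, window = 20L) {
  window <- as.integer(window)
  n <- length(signal)
  if (n <= window)
    stop("signal length must exceed the window (", window, ")", call. = FALSE)
  (signal[(window + 1L):n] - signal[1L:(n - window)]) / window
}

# Pearson r between the F3 and F4 segments of every window, vectorized via
# rolling sums.
.window_correlation <- function(a, b, w) {
  n <- length(a)
  roll <- function(x) {
    cs <- cumsum(c(0, x))
    cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]
  }
  sa <- roll(a); sb <- roll(b)
  saa <- roll(a^2); sbb <- roll(b^2); sab <- roll(a * b)
  cov <- sab - sa * sb / w
  va <- saa - sa^2 / w
  vb <- sbb - sb^2 / w
  r <- rep(NA_real_, length(cov))
  ok <- va > 0 & vb > 0
  r[ok] <- cov[ok] / sqrt(va[ok] * vb[ok])
  r
}

#' Detect lateral eye movements from the F3/F4 channel pair
#'
#' Runs the slope-and-anticorrelation detector on the raw (unfiltered) F3 and
#' F4 channels of a recording.  A window starting at sample i is a detection
#' when |K_i| exceeds the slope threshold on both channels (configurable to
#' either), the two slopes have opposite signs, and the window Pearson
#' correlation of F3 and F4 is below -r_threshold.  Runs of detections
#' within the refractory period merge into single events.  Common-mode
#' deflections such as blinks produce positive F3/F4 correlation and are
#' rejected by the anticorrelation gate.
#'
#' @param rec An \code{eeg_recording} containing channels F3 and F4.
#' @param params A \code{\link{detector_params}}.
#' @return A data.frame of events: \code{onset_sample}, \code{offset_sample}
#'   (0-based start indices of the first and last firing window),
#'   \code{onset_s}, \code{offset_s}, \code{direction}, \code{K_f3},
#'   \code{K_f4}, \code{r_window} (values at the peak-|K| window).
#' @export
detect_events <- function(rec, params = detector_params()) {
  stopifnot(inherits(rec, "eeg_recording"))
  for (ch in c("F3", "F4"))
    if (!ch %in% rec$channel_labels)
      stop("channel ", ch, " required for eye-movement detection",
           call. = FALSE)
  f3 <- rec$samples["F3", ]
  f4 <- rec$samples["F4", ]
  w <- params$window
  k3 <- slope_series(f3, w)
  k4 <- slope_series(f4, w)
  # window [i, i+w] spans w+1 samples; correlate that same span
  r <- .window_correlation(f3, f4, w + 1L)[seq_along(k3)]
  above <- if (params$both_channels)
    abs(k3) > params$k_threshold & abs(k4) > params$k_threshold
  else
    abs(k3) > params$k_threshold | abs(k4) > params$k_threshold
  hit <- above & (sign(k3) * sign(k4) < 0) &
    !is.na(r) & (r < -params$r_threshold)
  idx <- which(hit)
  if (!length(idx)) return(.empty_events())
  gap <- max(1L, round(params$refractory * rec$fs))
  brk <- c(TRUE, diff(idx) > gap)
  grp <- cumsum(brk)
  out <- lapply(split(idx, grp), function(ix) {
    peak <- ix[which.max(pmin(abs(k3[ix]), abs(k4[ix])))]
    dir_ <- if (k3[peak] > 0) params$f3_positive
      else setdiff(c("left", "right"), params$f3_positive)
    data.frame(onset_sample = ix[1] - 1L, offset_sample = ix[length(ix)] - 1L,
               onset_s = (ix[1] - 1L) / rec$fs,
               offset_s = (ix[length(ix)] - 1L) / rec$fs,
               direction = dir_, K_f3 = k3[peak], K_f4 = k4[peak],
               r_window = r[peak], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.empty_events <- function() {
  data.frame(onset_sample = integer(0), offset_sample = integer(0),
             onset_s = numeric(0), offset_s = numeric(0),
             direction = character(0), K_f3 = numeric(0), K_f4 = numeric(0),
             r_window = numeric(0), stringsAsFactors = FALSE)
}

#' Eye movements per minute
#'
#' @param events Event data.frame from \code{\link{detect_events}} (or any
#'   object with one row per event).
#' @param duration Recording duration in seconds (> 0).
#' @return Events per minute.
#' @export
eye_rate <- function(events, duration) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  n <- if (is.data.frame(events)) nrow(events) else length(events)
  60 * n / duration
}

#' Match detected events against ground truth
#'
#' A truth event counts as recovered when some detection overlaps its span
#' (widened by \code{tol_samples} on both sides); a detection is a false
#' positive when it overlaps no truth event at all.  Used by the
#' simulation-based detector validation.
#'
#' @param detected Data.frame from \code{\link{detect_events}}.
#' @param truth Ground-truth data.frame (\code{onset_sample},
#'   \code{offset_sample}) from \code{\link{simulate_epoch}}.
#' @param tol_samples Matching tolerance in samples (default 20, one window).
#' @return List with \code{recall} (NA when there is no truth event),
#'   \code{n_true_positive}, \code{n_false_positive}, \code{n_truth}.
#' @export
match_events <- function(detected, truth, tol_samples = 20L) {
  if (nrow(truth) == 0)
    return(list(recall = NA_real_, n_true_positive = 0L,
                n_false_positive = nrow(detected), n_truth = 0L))
  overlaps <- function(d_on, d_off)
    d_on <= truth$offset_sample + tol_samples &
      d_off >= truth$onset_sample - tol_samples
  hit_truth <- rep(FALSE, nrow(truth))
  fp <- 0L
  for (i in seq_len(nrow(detected))) {
    j <- overlaps(detected$onset_sample[i], detected$offset_sample[i])
    if (any(j)) hit_truth <- hit_truth | j else fp <- fp + 1L
  }
  list(recall = mean(hit_truth), n_true_positive = sum(hit_truth),
       n_false_positive = fp, n_truth = nrow(truth))
}
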