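# Orthonormal Daubechies scaling filters (minimum-phase), by vanishing
# moments.  db16 is the package default: at a 4-level decomposition its
# transition bands are narrow enough that a mid-node tone keeps >95% of its
# energy in one 4 Hz node and cross-band leakage near the alpha/beta boundary
# stays small; shorter members (db2-db10) are progressively blunter and are
# kept selectable for short fixtures.
.db_filters <- list(
  db2 = c(0.48296291314469025, 0.83651630373746899,
          0.22414386804185735, -0.12940952255092145),
  db4 = c(0.23037781330885523, 0.71484657055254153,
          0.63088076792959036, -0.02798376941698385,
          -0.18703481171888114, 0.03084138183598697,
          0.03288301166698295, -0.01059740178499728),
  db8 = c(0.05441584224310401, 0.31287159091429995,
          0.67563073629728976, 0.58535468365420671,
          -0.01582910525634931, -0.28401554296154692,
          0.00047248457391328, 0.12874742662047847,
          -0.01736930100180755, -0.04408825393079475,
          0.01398102791739828, 0.00874609404740578,
          -0.00487035299345157, -0.00039174037337695,
          0.00067544940645057, -0.00011747678412477),
  db10 = c(0.02667005790055555, 0.18817680007769148,
           0.52720118893172558, 0.68845903945360348,
           0.28117234366057746, -0.24984642432731538,
           -0.19594627437737705, 0.12736934033579325,
           0.09305736460357235, -0.07139414716639708,
           -0.02945753682187581, 0.03321267405934100,
           0.00360655356695617, -0.01073317548333057,
           0.00139535174705290, 0.00199240529518505,
           -0.00068585669495971, -0.00011646685512929,
           0.00009358867032007, -0.00001326420289452)
,
  db16 = c(
           0.0031892209253477381, 0.034907714323673344,
           0.16506428348885313, 0.4303127228460038,
           0.63735633208378895, 0.44029025688635692,
           -0.089751089402489645, -0.32706331052791771,
           -0.027918208133028276, 0.2111906939471043,
           0.027340263752716042, -0.1323883055638104,
           -0.006239722752474872, 0.075924236044276311,
           -0.0075889743688577378, -0.036888397691730142,
           0.01029765964095597, 0.013993768859828731,
           -0.0069900145634139163, -0.0036442796214983899,
           0.003128023381206269, 0.00040789698084971285,
           -0.00094102174935956756, 0.00011424152003872239,
           0.00017478724522533817, -6.103596621410936e-05,
           -1.3945668988208893e-05, 1.1336608661276258e-05,
           -1.0435713423116066e-06, -7.3636567854512051e-07,
           2.3087840868575457e-07, -2.1093396301007431e-08)
)

.scaling_filter <- function(wavelet) {
  h <- .db_filters[[wavelet]]
  if (is.null(h))
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(.db_filters), collapse = ", "), call. = FALSE)
  h
}

# quadrature mirror filter g[n] = (-1)^n h[L-1-n] (0-based n)
.wavelet_filter <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1)
}

# Periodized analysis step on a matrix (samples x channels): circular
# correlation with the filter followed by dyadic downsampling.  Columns are
# processed simultaneously; nrow(x) must be even.
.pconv_down <- function(x, f) {
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  for (k in seq_along(f)) {
    idx <- ((seq_len(n) - 1L + (k - 1L)) %% n) + 1L
    out <- out + f[k] * x[idx, , drop = FALSE]
  }
  out[seq(1L, n, by = 2L), , drop = FALSE]
}

# Adjoint of .pconv_down: dyadic upsampling then circular convolution.
.up_pconv <- function(a, f, n) {
  u <- matrix(0, n, ncol(a))
  u[seq(1L, n, by = 2L), ] <- a
  out <- matrix(0, n, ncol(a))
  for (k in seq_along(f)) {
    idx <- ((seq_len(n) - 1L - (k - 1L)) %% n) + 1L
    out <- out + f[k] * u[idx, , drop = FALSE]
  }
  out
}

# Full wavelet-packet analysis to `level`.  Returns terminal-node coefficient
# matrices in natural (Paley) order together with the frequency interval each
# node covers.  Highpass-plus-downsample flips the spectral orientation of a
# node, so a node's flag tracks whether its children map to the lower or upper
# half of its band.
.wp_analyze <- function(x, level, h) {
  g <- .wavelet_filter(h)
  fs2 <- 0.5 # frequencies as fractions of Nyquist; scaled by caller
  nodes <- list(list(coef = x, lo = 0, hi = 1, flipped = FALSE))
  for (lev in seq_len(level)) {
    nxt <- vector("list", 2L * length(nodes))
    for (j in seq_along(nodes)) {
      nd <- nodes[[j]]
      a <- .pconv_down(nd$coef, h)
      d <- .pconv_down(nd$coef, g)
      mid <- (nd$lo + nd$hi) / 2
      if (!nd$flipped) {
        lo_child <- list(coef = a, lo = nd$lo, hi = mid, flipped = FALSE)
        hi_child <- list(coef = d, lo = mid, hi = nd$hi, flipped = TRUE)
      } else {
        lo_child <- list(coef = a, lo = mid, hi = nd$hi, flipped = TRUE)
        hi_child <- list(coef = d, lo = nd$lo, hi = mid, flipped = FALSE)
      }
      nxt[[2L * j - 1L]] <- lo_child
      nxt[[2L * j]] <- hi_child
    }
    nodes <- nxt
  }
  nodes
}

# Inverse transform from a subset of terminal nodes (others implicitly zero).
# `keep` is a logical vector over natural-order terminal nodes.
.wp_synthesize <- function(nodes, keep, level, h, n, nchan) {
  g <- .wavelet_filter(h)
  cur <- lapply(seq_along(nodes), function(j) {
    if (keep[j]) nodes[[j]]$coef else NULL
  })
  for (lev in seq_len(level)) {
    m <- length(cur) / 2L
    len <- n / 2^(level - lev)
    nxt <- vector("list", m)
    for (j in seq_len(m)) {
      a <- cur[[2L * j - 1L]]
      d <- cur[[2L * j]]
      if (is.null(a) && is.null(d)) next
      acc <- matrix(0, len, nchan)
      if (!is.null(a)) acc <- acc + .up_pconv(a, h, len)
      if (!is.null(d)) acc <- acc + .up_pconv(d, g, len)
      nxt[[j]] <- acc
    }
    cur <- nxt
  }
  if (is.null(cur[[1L]])) matrix(0, n, nchan) else cur[[1L]]
}

#' Wavelet-packet decomposition of a multichannel recording
#'
#' Decomposes every channel of a recording into \code{2^level} equal-width
#' frequency nodes with an orthonormal, periodized wavelet-packet transform,
#' and reports the energy captured by each terminal node.  At the default
#' 4-level depth and a 128 Hz working rate the 16 nodes are 4 Hz wide, so the
#' theta band (4-8 Hz) is exactly one node.  Because the transform is
#' orthonormal, node energies sum to the total signal energy (Parseval).
#'
#' Signals whose length is not a multiple of \code{2^level} are zero-padded at
#' the tail for the transform; reconstructions are truncated back to the
#' original length.
#'
#' @param rec An \code{eeg_recording}, or a plain numeric matrix
#'   (channels x time) with an \code{fs} attribute or \code{fs} argument.
#' @param level Decomposition depth (default 4).
#' @param wavelet Wavelet family name; one of \code{"db2"}, \code{"db4"}, \code{"db8"}, \code{"db10"}, \code{"db16"} (default).
#' @param fs Sampling rate, required only when \code{rec} is a bare matrix.
#' @return A \code{band_set} object: per-channel node energies
#'   (\code{2^level} x channels, in ascending frequency order), node frequency
#'   intervals in Hz, and the machinery needed by \code{\link{extract_band}}.
#' @examples
#' x <- matrix(sin(2 * pi * 6 * (0:1023) / 128), nrow = 1)
#' bs <- wpd_decompose(x, fs = 128)
#' # energy concentrates in the 4-8 Hz node
#' which.max(rowSums(bs$node_energies))
#' @export
wpd_decompose <- function(rec, level = 4L, wavelet = "db16", fs = NULL) {
  if (inherits(rec, "eeg_recording")) {
    samples <- rec$samples
    fs <- rec$fs
    labels <- rec$channel_labels
  } else {
    samples <- as.matrix(rec)
    if (is.null(fs)) fs <- attr(rec, "fs")
    if (is.null(fs)) stop("fs must be supplied for a bare matrix", call. = FALSE)
    labels <- rownames(samples)
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(samples)))
  }
  level <- as.integer(level)
  if (level < 1L) stop("level must be >= 1", call. = FALSE)
  h <- .scaling_filter(wavelet)
  n0 <- ncol(samples)
  if (n0 < length(h) * 2^level)
    stop("signal too short for a level-", level, " decomposition", call. = FALSE)
  block <- 2^level
  n <- ceiling(n0 / block) * block
  x <- t(samples)
  if (n > n0) x <- rbind(x, matrix(0, n - n0, ncol(x)))

  nodes <- .wp_analyze(x, level, h)
  # ascending frequency order of natural-order terminal nodes
  lo <- vapply(nodes, `[[`, numeric(1), "lo") * fs / 2
  hi <- vapply(nodes, `[[`, numeric(1), "hi") * fs / 2
  ord <- order(lo)
  energies <- vapply(nodes, function(nd) colSums(nd$coef^2), numeric(ncol(x)))
  energies <- if (is.matrix(energies)) t(energies) else matrix(energies, ncol = 1)
  energies <- energies[ord, , drop = FALSE]         # node x channel
  colnames(energies) <- labels
  structure(list(
    node_energies = energies,
    node_freqs = cbind(lo = lo[ord], hi = hi[ord]),
    channel_labels = labels,
    level = level, wavelet = wavelet, fs = fs,
    n_samples = n0, n_padded = n,
    .nodes = nodes, .order = ord
  ), class = "band_set")
}

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("Wavelet-packet band set: level %d (%s), %d nodes of %.3g Hz, %d channel(s), fs = %g Hz\n",
              x$level, x$wavelet, nrow(x$node_freqs),
              x$node_freqs[1, 2] - x$node_freqs[1, 1],
              length(x$channel_labels), x$fs))
  invisible(x)
}

#' Canonical EEG analysis bands
#'
#' Frequency intervals (Hz) for the theta, alpha and beta rhythms as used
#' throughout the pipeline: theta 4-8, alpha 8-14, beta 14-32.
#' @export
band_definitions <- function() {
  list(theta = c(4, 8), alpha = c(8, 14), beta = c(14, 32))
}

# Map a band to terminal nodes.  rule = "majority": include a node when more
# than half of its interval lies inside the band (so a node straddling the
# band edge with exactly 50% overlap is excluded); rule = "any": include on
# any positive overlap.
.band_nodes <- function(bs, band_range, rule = c("majority", "any")) {
  rule <- match.arg(rule)
  lo <- bs$node_freqs[, "lo"]; hi <- bs$node_freqs[, "hi"]
  ovl <- pmax(0, pmin(hi, band_range[2]) - pmax(lo, band_range[1]))
  frac <- ovl / (hi - lo)
  if (rule == "majority") frac > 0.5 else frac > 0
}

#' Reconstruct a frequency band from wavelet-packet nodes
#'
#' Rebuilds the time-domain signal carried by the terminal nodes whose
#' frequency intervals fall (by majority overlap, by default) inside the
#' requested band.  \code{band = "all"} reconstructs from every node and
#' recovers the original signal to numerical precision.
#'
#' @param bs A \code{band_set} from \code{\link{wpd_decompose}}.
#' @param band One of \code{"theta"}, \code{"alpha"}, \code{"beta"},
#'   \code{"all"}, or a numeric length-2 interval in Hz.
#' @param rule Node-overlap rule, \code{"majority"} (default) or \code{"any"}.
#' @return A channels x time matrix of the band-limited signal (microvolts),
#'   the same shape as the decomposed samples.
#' @export
extract_band <- function(bs, band, rule = c("majority", "any")) {
  stopifnot(inherits(bs, "band_set"))
  rule <- match.arg(rule)
  if (identical(band, "all")) {
    keep_f <- rep(TRUE, nrow(bs$node_freqs))
  } else {
    if (is.character(band)) {
      defs <- band_definitions()
      if (!band %in% names(defs))
        stop("unknown band '", band, "'", call. = FALSE)
      band <- defs[[band]]
    }
    if (band[1] >= bs$fs / 2)
      stop("band lies entirely above the Nyquist frequency (",
           bs$fs / 2, " Hz)", call. = FALSE)
    keep_f <- .band_nodes(bs, band, rule)
  }
  # keep_f is in frequency order; map back to natural node order
  keep <- logical(length(keep_f))
  keep[bs$.order] <- keep_f
  h <- .scaling_filter(bs$wavelet)
  y <- .wp_synthesize(bs$.nodes, keep, bs$level, h,
                      bs$n_padded, length(bs$channel_labels))
  out <- t(y[seq_len(bs$n_samples), , drop = FALSE])
  rownames(out) <- bs$channel_labels
  out
}

#' Mean squared amplitude of a band-limited signal
#'
#' The band power is the mean of squared sample amplitudes (microvolts
#' squared), averaged over channels unless a channel subset is requested.
#'
#' @param band_signal Channels x time matrix (or a single-channel vector).
#' @param channels Optional character vector of row names to restrict to.
#' @return Scalar mean squared amplitude.
#' @export
band_power <- function(band_signal, channels = NULL) {
  if (is.null(dim(band_signal)))
    band_signal <- matrix(band_signal, nrow = 1)
  if (ncol(band_signal) == 0 || nrow(band_signal) == 0)
    stop("empty signal", call. = FALSE)
  if (!is.null(channels)) {
    miss <- setdiff(channels, rownames(band_signal))
    if (length(miss))
      stop("unknown channel(s): ", paste(miss, collapse = ", "), call. = FALSE)
    band_signal <- band_signal[channels, , drop = FALSE]
  }
  mean(band_signal^2)
}

#' Resample a recording to a lower working rate
#'
#' The 4-level wavelet-packet analysis needs a working rate at which its
#' terminal nodes resolve the theta band; 128 Hz gives 4 Hz nodes with
#' beta (<= 32 Hz) below Nyquist.  Polyphase resampling is delegated to
#' \code{signal::resample}.
#'
#' @param rec An \code{eeg_recording}.
#' @param fs_target Target rate in Hz (default 128).
#' @return A new \code{eeg_recording} at \code{fs_target}.
#' @export
resample_recording <- function(rec, fs_target = 128) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs == fs_target) return(rec)
  frac <- .simplify_ratio(fs_target, rec$fs)
  out <- t(apply(rec$samples, 1, function(x)
    signal::resample(x, p = frac[1], q = frac[2])))
  eeg_recording(out, fs = fs_target, channel_labels = rec$channel_labels,
                subject_id = rec$subject_id, condition = rec$condition,
                stage = rec$stage)
}

.simplify_ratio <- function(p, q) {
  # integer p/q from possibly non-integer rates
  scale <- 1
  while (abs(p * scale - round(p * scale)) > 1e-9 ||
         abs(q * scale - round(q * scale)) > 1e-9) scale <- scale * 10
  p <- round(p * scale); q <- round(q * scale)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p / d, q / d)
}
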