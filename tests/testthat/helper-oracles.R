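# Independent oracles for graph metrics, deliberately using different
# algorithms from the package (triangle enumeration instead of neighbour
# submatrix sums; Floyd-Warshall instead of BFS level expansion).

oracle_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    d <- length(nb)
    if (d < 2) next
    e <- 0
    for (a in seq_len(d - 1))
      for (b in (a + 1):d)
        if (A[nb[a], nb[b]] == 1) e <- e + 1
    ci[i] <- e / (d * (d - 1) / 2)
  }
  list(C_per_node = ci, C = mean(ci))
}

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

oracle_L_G <- function(A) {
  D <- oracle_distances(A)
  off <- D[row(D) != col(D)]
  fin <- is.finite(off)
  list(L = if (any(fin)) mean(off[fin]) else NA_real_,
       G = if (length(off)) mean(ifelse(fin, 1 / off, 0)) else 0)
}

# wrap a plain adjacency matrix as a brain_network
as_net <- function(A, labels = paste0("n", seq_len(nrow(A)))) {
  dimnames(A) <- list(labels, labels)
  structure(list(labels = labels, adjacency = A, threshold = 0.5),
            class = "brain_network")
}

random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- stats::rbinom(sum(up), 1, p)
  A + t(A)
}

# adjacency matrix from the bits of an integer code (exhaustive enumeration)
adjacency_from_code <- function(n, code) {
  m <- n * (n - 1) / 2
  bits <- as.integer(intToBits(code))[seq_len(m)]
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- bits
  A + t(A)
}

# FFT periodogram energy of a signal inside [lo, hi) Hz
spectral_band_energy <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # fold to [0, fs/2]
  sum(p[f >= lo & f < hi])
}

# a quiet recording with known content on the study montage
make_recording <- function(n = 512, fs = 128, signal_fun = NULL) {
  chans <- study_channels()
  x <- matrix(0, length(chans), n)
  if (!is.null(signal_fun))
    for (i in seq_along(chans)) x[i, ] <- signal_fun(i, n, fs)
  eeg_recording(x, fs = fs, channel_labels = chans,
                subject_id = "S01", condition = "normal", stage = 1L)
}

tiny_cfg <- function(seed = 1, ...) {
  sim_config(n_subjects = 2, stages = 3, fs = 128, epoch_seconds = 10,
             seed = seed, ...)
}
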