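#' Pearson correlation matrix of band-limited channel signals
#'
#' Sample Pearson coefficients (n-1 normalization) between every unordered
#' pair of channels, the adjacency precursor of the functional brain network.
#'
#' @param band_signals Channels x time matrix (typically the theta-band
#'   reconstruction from \code{\link{extract_band}}).
#' @param labels Channel labels; defaults to row names.
#' @return A \code{corr_matrix} object wrapping the symmetric coefficient
#'   matrix with unit diagonal.
#' @export
correlation_matrix <- function(band_signals, labels = rownames(band_signals)) {
  x <- as.matrix(band_signals)
  if (ncol(x) < 2) stop("need at least 2 samples per channel", call. = FALSE)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(x)))
  v <- apply(x, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance channel(s): ",
         paste(labels[v == 0], collapse = ", "), call. = FALSE)
  r <- stats::cor(t(x))
  dimnames(r) <- list(labels, labels)
  structure(list(labels = labels, r = r), class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("Channel correlation matrix (%d x %d), off-diagonal range [%.3f, %.3f]\n",
              nrow(x$r), ncol(x$r),
              min(x$r[upper.tri(x$r)]), max(x$r[upper.tri(x$r)])))
  invisible(x)
}

#' Threshold a correlation matrix into a binary brain network
#'
#' An edge joins channels i and j when their correlation strictly exceeds the
#' threshold T (signed comparison by default: strong negative correlations do
#' not form edges; set \code{abs_corr = TRUE} for the |r| > T variant).
#'
#' @param corr A \code{corr_matrix}.
#' @param T Threshold in (0, 1).
#' @param abs_corr Compare |r| rather than r against T.
#' @return A \code{brain_network}: binary symmetric adjacency with zero
#'   diagonal, plus the threshold used.
#' @export
build_adjacency <- function(corr, T, abs_corr = FALSE) {
  stopifnot(inherits(corr, "corr_matrix"))
  if (!is.numeric(T) || length(T) != 1 || T <= 0 || T >= 1)
    stop("threshold T must lie in (0, 1)", call. = FALSE)
  r <- if (abs_corr) abs(corr$r) else corr$r
  adj <- (r > T) * 1
  diag(adj) <- 0
  structure(list(labels = corr$labels, adjacency = adj, threshold = T),
            class = "brain_network")
}

#' @export
print.brain_network <- function(x, ...) {
  cat(sprintf("Brain network: %d nodes, %d edges (T = %g)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$threshold))
  invisible(x)
}

#' Edge count of a brain network
#' @param net A \code{brain_network}.
#' @export
edge_count <- function(net) sum(net$adjacency) / 2

#' Clustering coefficients of a brain network
#'
#' Per node, the fraction of realized edges among its neighbours:
#' C_i = E_i / (D_i (D_i - 1) / 2), where D_i is the degree of node i and E_i
#' the number of edges among its neighbours.  Nodes of degree < 2, for which
#' the ratio is 0/0, are assigned C_i = 0.  The network-level C is the
#' unweighted mean over all nodes.
#'
#' @param net A \code{brain_network}.
#' @return List with \code{C_per_node} (named vector) and \code{C} (mean).
#' @export
clustering_coefficient <- function(net) {
  A <- net$adjacency
  n <- nrow(A)
  ci <- numeric(n)
  deg <- rowSums(A)
  for (i in seq_len(n)) {
    if (deg[i] < 2) next
    nb <- which(A[i, ] > 0)
    e_i <- sum(A[nb, nb]) / 2
    ci[i] <- e_i / (deg[i] * (deg[i] - 1) / 2)
  }
  names(ci) <- net$labels
  list(C_per_node = ci, C = mean(ci))
}

# All-pairs shortest path lengths on a binary undirected graph by
# simultaneous breadth-first level expansion (boolean matrix products).
.bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n) > 0
  frontier <- A > 0
  d <- 1
  while (any(frontier & !reach)) {
    newly <- frontier & !reach
    D[newly] <- d
    reach <- reach | frontier
    frontier <- (frontier %*% A) > 0
    d <- d + 1
    if (d > n) break
  }
  D
}

#' Characteristic path length and global efficiency
#'
#' Shortest path lengths are computed on the unweighted graph by
#' breadth-first expansion.  L is the mean shortest path over ordered pairs
#' of distinct nodes that are connected (disconnected pairs are excluded and
#' counted separately); G is the mean of 1/L_ij over all ordered pairs, with
#' 1/infinity = 0 for disconnected pairs, so G = 1 for a complete graph and
#' 0 for an empty one.
#'
#' @param net A \code{brain_network}.
#' @return List with \code{L} (NA when no pair is connected), \code{G},
#'   \code{n_finite_pairs} and \code{n_disconnected_pairs} (ordered pairs).
#' @export
path_length_and_efficiency <- function(net) {
  A <- net$adjacency
  n <- nrow(A)
  if (n < 2) return(list(L = NA_real_, G = 0, n_finite_pairs = 0L,
                         n_disconnected_pairs = 0L))
  D <- .bfs_distances(A)
  off <- D[row(D) != col(D)]
  finite <- is.finite(off)
  L <- if (any(finite)) mean(off[finite]) else NA_real_
  G <- mean(ifelse(finite, 1 / off, 0))
  list(L = L, G = G, n_finite_pairs = sum(finite),
       n_disconnected_pairs = sum(!finite))
}

#' All network metrics of a thresholded brain network
#'
#' @param net A \code{brain_network}.
#' @return List with \code{C_per_node}, \code{C}, \code{L}, \code{G},
#'   \code{n_edges}.
#' @export
network_metrics <- function(net) {
  cc <- clustering_coefficient(net)
  pe <- path_length_and_efficiency(net)
  list(C_per_node = cc$C_per_node, C = cc$C, L = pe$L, G = pe$G,
       n_edges = edge_count(net))
}

#' Default threshold grid for the significance sweep
#'
#' Thresholds 0.01, 0.035, ..., 0.485: increments of 0.025 across the open
#' interval (0.01 - eps, 0.51).
#' @export
threshold_grid <- function() seq(0.01, 0.4851, by = 0.025)

#' Data-driven selection of the network threshold
#'
#' Implements the significance sweep: for each candidate threshold T, each
#' subject's stage-wise C and G are compared (stage 1 versus each later
#' stage) with two-tailed t tests across subjects.  A grid value is
#' "significant" for a metric when every stage-1-vs-stage-k comparison has
#' p < alpha; the metric's significant interval is the maximal contiguous run
#' of significant grid values.  The selected threshold is the midpoint of the
#' intersection of the C and G intervals.
#'
#' @param metric_samples Data.frame with columns \code{T}, \code{subject},
#'   \code{stage}, \code{C}, \code{G}: per-subject metrics computed at every
#'   grid threshold (see \code{\link{sweep_metric_samples}}).
#' @param grid Threshold grid (default \code{\link{threshold_grid}}).
#' @param alpha Significance level (default 0.05).
#' @param design t-test design passed to \code{\link{t_test}}.
#' @return A \code{threshold_sweep} object: \code{stat_table} (one row per
#'   threshold x metric x comparison), \code{interval_C},
#'   \code{interval_G}, \code{selected_T} (NA when either interval is empty
#'   or they do not intersect).
#' @export
sweep_threshold <- function(metric_samples, grid = threshold_grid(),
                            alpha = 0.05, design = "independent_pooled") {
  stages <- sort(unique(metric_samples$stage))
  if (length(stages) < 2) stop("need at least 2 stages", call. = FALSE)
  if (length(unique(metric_samples$subject)) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  base_stage <- stages[1]
  rows <- list()
  sig <- list(C = rep(TRUE, length(grid)), G = rep(TRUE, length(grid)))
  for (gi in seq_along(grid)) {
    at_t <- metric_samples[abs(metric_samples$T - grid[gi]) < 1e-9, ]
    s1 <- at_t[at_t$stage == base_stage, ]
    for (k in stages[-1]) {
      sk <- at_t[at_t$stage == k, ]
      for (m in c("C", "G")) {
        tt <- t_test(s1[[m]], sk[[m]], design = design, alpha = alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          T = grid[gi], metric = m, comparison = paste0(base_stage, "v", k),
          t = tt$t, df = tt$df, p = tt$p, significant = tt$significant)
        if (!isTRUE(tt$significant)) sig[[m]][gi] <- FALSE
      }
    }
  }
  stat_table <- do.call(rbind, rows)
  interval_C <- .max_run_interval(grid, sig$C)
  interval_G <- .max_run_interval(grid, sig$G)
  sel <- select_threshold(interval_C, interval_G)
  structure(list(thresholds = grid, stat_table = stat_table,
                 significant_interval_C = interval_C,
                 significant_interval_G = interval_G,
                 selected_T = sel, alpha = alpha),
            class = "threshold_sweep")
}

# longest contiguous run of TRUE grid points, as [min, max] or NULL
.max_run_interval <- function(grid, ok) {
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_runs <- which(r$values)
  best <- true_runs[which.max(r$lengths[true_runs])]
  c(grid[starts[best]], grid[ends[best]])
}

#' Midpoint threshold from two significant intervals
#'
#' The selected network threshold is the mean of the endpoints of the
#' intersection of the C and G significant intervals, e.g. intersecting
#' intervals ending at [0.26, 0.435] select T = 0.3475.
#'
#' @param interval_C,interval_G Length-2 numeric intervals (or NULL).
#' @return Scalar threshold, or NA when either interval is empty or they do
#'   not overlap.
#' @export
select_threshold <- function(interval_C, interval_G) {
  if (is.null(interval_C) || is.null(interval_G)) return(NA_real_)
  lo <- max(interval_C[1], interval_G[1])
  hi <- min(interval_C[2], interval_G[2])
  if (lo > hi) return(NA_real_)
  (lo + hi) / 2
}

#' @export
print.threshold_sweep <- function(x, ...) {
  fmt <- function(iv) if (is.null(iv)) "empty"
    else sprintf("[%.3f, %.3f]", iv[1], iv[2])
  cat("Threshold significance sweep\n")
  cat("  C interval:", fmt(x$significant_interval_C), "\n")
  cat("  G interval:", fmt(x$significant_interval_G), "\n")
  if (is.na(x$selected_T))
    cat("  no threshold selected (empty or disjoint intervals)\n")
  else cat(sprintf("  selected T = %.4f\n", x$selected_T))
  invisible(x)
}

#' Per-subject network metrics across a threshold grid
#'
#' Computes C and G for every subject x stage correlation matrix at every
#' grid threshold — the input for \code{\link{sweep_threshold}}.
#'
#' @param corr_list Named list of \code{corr_matrix} objects; names or the
#'   accompanying \code{meta} data.frame give subject and stage.
#' @param meta Data.frame with columns \code{subject} and \code{stage},
#'   one row per element of \code{corr_list}.
#' @param grid Threshold grid.
#' @return Data.frame with columns \code{T}, \code{subject}, \code{stage},
#'   \code{C}, \code{G}.
#' @export
sweep_metric_samples <- function(corr_list, meta, grid = threshold_grid()) {
  stopifnot(length(corr_list) == nrow(meta))
  out <- vector("list", length(corr_list) * length(grid))
  k <- 0L
  for (i in seq_along(corr_list)) {
    for (gi in seq_along(grid)) {
      net <- build_adjacency(corr_list[[i]], grid[gi])
      m <- network_metrics(net)
      k <- k + 1L
      out[[k]] <- data.frame(T = grid[gi], subject = meta$subject[i],
                             stage = meta$stage[i], C = m$C, G = m$G)
    }
  }
  do.call(rbind, out)
}
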