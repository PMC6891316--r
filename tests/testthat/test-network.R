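test_that("correlation matrix matches direct evaluation of the sample formula", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  # direct formula: (sum xy - n xbar ybar) / ((n-1) sx sy)
  n <- 4
  r_direct <- (sum(x * y) - n * mean(x) * mean(y)) /
    ((n - 1) * sd(x) * sd(y))
  cm <- correlation_matrix(rbind(a = x, b = y))
  expect_equal(cm$r["a", "b"], r_direct, tolerance = 1e-12)
  expect_equal(diag(cm$r), c(a = 1, b = 1))
  cm2 <- correlation_matrix(rbind(a = x, b = -x + 0.5))
  expect_equal(cm2$r["a", "b"], -1)
  expect_error(correlation_matrix(rbind(a = x, b = rep(2, 4))),
               "zero-variance.*b")
  expect_error(correlation_matrix(matrix(1:2, 2, 1)), "2 samples")
})

test_that("adjacency follows the strict r > T rule", {
  mk <- function(v) {
    r <- matrix(v, 3, 3); diag(r) <- 1
    structure(list(labels = c("a", "b", "c"), r = r), class = "corr_matrix")
  }
  expect_equal(edge_count(build_adjacency(mk(0.9), 0.3475)), 3)
  expect_equal(edge_count(build_adjacency(mk(0.1), 0.3475)), 0)
  # boundary: r exactly equal to T gives no edge
  expect_equal(edge_count(build_adjacency(mk(0.3475), 0.3475)), 0)
  # signed rule: strong negative correlations are not edges unless abs_corr
  expect_equal(edge_count(build_adjacency(mk(-0.9), 0.3475)), 0)
  expect_equal(edge_count(build_adjacency(mk(-0.9), 0.3475, abs_corr = TRUE)),
               3)
  expect_error(build_adjacency(mk(0.5), 1.2), "T must lie")
})

test_that("closed-form graphs give the expected metrics", {
  K14 <- as_net(matrix(1, 14, 14) - diag(14))
  m <- network_metrics(K14)
  expect_equal(m$C, 1)
  expect_equal(m$G, 1)
  expect_equal(m$L, 1)
  expect_equal(m$n_edges, 91)

  empty <- as_net(matrix(0, 5, 5))
  me <- network_metrics(empty)
  expect_equal(me$G, 0)
  expect_true(is.na(me$L))
  expect_identical(path_length_and_efficiency(empty)$n_finite_pairs, 0L)

  star <- matrix(0, 14, 14); star[1, 2:14] <- 1; star <- star + t(star)
  expect_equal(clustering_coefficient(as_net(star))$C, 0)

  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1
  path3 <- path3 + t(path3)
  expect_equal(path_length_and_efficiency(as_net(path3))$G, 5 / 6)
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(1)
  for (i in 1:200) {
    n <- sample(3:10, 1)
    A <- random_adjacency(n, runif(1, 0.1, 0.9))
    net <- as_net(A)
    cc <- clustering_coefficient(net)
    oc <- oracle_clustering(A)
    expect_equal(unname(cc$C_per_node), oc$C_per_node)
    pe <- path_length_and_efficiency(net)
    og <- oracle_L_G(A)
    expect_equal(pe$L, og$L)
    expect_equal(pe$G, og$G)
  }
})

test_that("metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(2)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    A <- random_adjacency(n, 0.5)
    net <- as_net(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    ig_c <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    # igraph reports NaN->0 handling via isolates; degree-1 nodes come back 0
    expect_equal(unname(clustering_coefficient(net)$C_per_node), ig_c)
    expect_equal(path_length_and_efficiency(net)$G,
                 igraph::global_efficiency(g))
  }
})

test_that("relabeling channels permutes node metrics and fixes globals", {
  set.seed(3)
  A <- random_adjacency(9, 0.4)
  perm <- sample(9)
  net <- as_net(A)
  net_p <- as_net(A[perm, perm])
  m <- network_metrics(net); mp <- network_metrics(net_p)
  expect_equal(unname(mp$C_per_node), unname(m$C_per_node[perm]))
  expect_equal(mp$C, m$C)
  expect_equal(mp$L, m$L)
  expect_equal(mp$G, m$G)
})

test_that("raising the threshold never adds edges and never raises G", {
  set.seed(4)
  r <- stats::cor(matrix(rnorm(40 * 8), 40))  # 8 channels, 40 samples
  cm <- structure(list(labels = paste0("c", 1:8), r = r),
                  class = "corr_matrix")
  grid <- seq(0.05, 0.9, by = 0.05)
  edges <- vapply(grid, function(T) edge_count(build_adjacency(cm, T)), 0)
  G <- vapply(grid, function(T)
    path_length_and_efficiency(build_adjacency(cm, T))$G, 0)
  expect_true(all(diff(edges) <= 0))
  expect_true(all(diff(G) <= 1e-12))
})

test_that("threshold sweep recovers a constructed significant interval", {
  grid <- threshold_grid()
  sig_C <- grid >= 0.235 - 1e-9 & grid <= 0.46 + 1e-9
  sig_G <- grid >= 0.26 - 1e-9 & grid <= 0.435 + 1e-9
  subj <- 1:6
  rows <- list()
  for (gi in seq_along(grid)) for (stg in 1:7) for (s in subj) {
    jit <- 0.001 * s
    rows[[length(rows) + 1L]] <- data.frame(
      T = grid[gi], subject = s, stage = stg,
      C = if (stg > 1 && sig_C[gi]) 0.5 + jit else 0.2 + jit,
      G = if (stg > 1 && sig_G[gi]) 0.6 + jit else 0.3 + jit)
  }
  samples <- do.call(rbind, rows)
  sw <- sweep_threshold(samples, grid = grid)
  expect_equal(sw$significant_interval_C, c(0.235, 0.46))
  expect_equal(sw$significant_interval_G, c(0.26, 0.435))
  expect_equal(sw$selected_T, 0.3475)
  # stat table covers every threshold x metric x comparison
  expect_equal(nrow(sw$stat_table), length(grid) * 2 * 6)
})

test_that("sweep handles degenerate and empty intervals", {
  expect_equal(select_threshold(c(0.31, 0.31), c(0.31, 0.31)), 0.31)
  expect_equal(select_threshold(c(0.235, 0.46), c(0.26, 0.435)), 0.3475)
  expect_true(is.na(select_threshold(NULL, c(0.2, 0.3))))
  expect_true(is.na(select_threshold(c(0.1, 0.2), c(0.3, 0.4))))

  # no stage separation anywhere: empty intervals, flagged selection
  grid <- threshold_grid()
  rows <- expand.grid(T = grid, subject = 1:4, stage = 1:3)
  set.seed(5)
  rows$C <- rnorm(nrow(rows)); rows$G <- rnorm(nrow(rows))
  sw <- sweep_threshold(rows, grid = grid, alpha = 1e-6)
  expect_null(sw$significant_interval_C)
  expect_true(is.na(sw$selected_T))
})
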