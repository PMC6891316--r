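test_that("pooled t test matches the direct formula", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  res <- t_test(a, b, design = "independent_pooled")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_direct <- (mean(a) - mean(b)) /
    sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_direct <- 2 * pt(-abs(t_direct), length(a) + length(b) - 2)
  expect_equal(res$t, t_direct)
  expect_equal(res$df, 8)
  expect_equal(res$p, p_direct)
  # symmetry and identity
  swapped <- t_test(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  same <- t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("degenerate zero-variance inputs are resolved, not raised", {
  eq <- t_test(rep(2, 4), rep(2, 5))
  expect_equal(eq$t, 0); expect_equal(eq$p, 1); expect_false(eq$degenerate)
  ne <- t_test(rep(3, 4), rep(2, 5))
  expect_true(ne$degenerate)
  expect_true(is.infinite(ne$t))
  expect_error(t_test(1, 1:3), "at least 2")
  expect_error(t_test(1:3, 1:4, design = "paired"), "equal sample lengths")
})

test_that("significance is consistent with the critical value", {
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6, mean = sample(c(0, 2), 1))
    res <- t_test(a, b)
    expect_identical(res$significant, res$p < 0.05)
    expect_identical(res$significant, abs(res$t) > res$t_crit)
  }
})

test_that("critical values match an independent quadrature of the t density", {
  dens_quantile <- function(alpha, df) {
    # integrate the density to find the two-tailed cutoff by bisection
    target <- 1 - alpha / 2
    f <- function(q) 0.5 + integrate(function(x) dt(x, df), 0, q,
                                     rel.tol = 1e-10)$value - target
    uniroot(f, c(0, 200), tol = 1e-12)$root
  }
  for (df in c(1, 2, 6, 12, 18, 22, 50, 100))
    expect_equal(critical_t(0.05, df), dens_quantile(0.05, df),
                 tolerance = 1e-4)
  expect_equal(critical_t(0.05, 1e6), qnorm(0.975), tolerance = 0.002)
  expect_error(critical_t(0, 5), "alpha")
  expect_error(critical_t(0.05, 0.5), "df")
})

test_that("t-test p values are uniform under the null", {
  set.seed(2024)
  p <- replicate(2000, t_test(rnorm(12), rnorm(12))$p)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  rej <- mean(p < 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 2000)
  expect_gte(rej, ci[1]); expect_lte(rej, ci[2])
})

test_that("stage trends report means, SDs and Spearman rho", {
  grid <- expand.grid(subject = sprintf("S%d", 1:4),
                      condition = c("normal", "mrm"), stage = 1:7,
                      stringsAsFactors = FALSE)
  grid$C <- grid$stage * 0.1 + runif(nrow(grid), 0, 0.01)
  grid$G <- 0.5
  grid$power_ratio <- 0.4; grid$eye_rate <- 5
  grid$sq_score <- 4L; grid$error_rate <- 0.1
  tab <- study_table(grid)
  tr <- stage_trend(tab, "C", "normal")
  expect_length(tr$stage_means, 7)
  expect_equal(tr$rho, 1)
  flat <- stage_trend(tab, "G", "normal")
  expect_equal(flat$rho, 0)
  expect_true(flat$tie_degenerate)
  expect_error(stage_trend(tab[tab$stage != 4, ], "C", "normal"),
               "missing stage")

  # permutation oracle: a strong injected trend is rarely beaten by chance
  obs <- tr$rho
  set.seed(6)
  beat <- mean(replicate(500, {
    abs(cor(1:7, sample(as.numeric(tr$stage_means)), method = "spearman"))
  }) >= abs(obs))
  expect_lt(beat, 0.05)
})

test_that("condition comparison uses the stage-mean pooled design", {
  grid <- expand.grid(subject = sprintf("S%d", 1:4),
                      condition = c("normal", "mrm"), stage = 1:7,
                      stringsAsFactors = FALSE)
  set.seed(10)
  grid$C <- ifelse(grid$condition == "normal", 0.5 + 0.05 * grid$stage,
                   0.5 + 0.01 * grid$stage) + rnorm(nrow(grid), 0, 0.005)
  grid$G <- grid$C; grid$power_ratio <- 0.4; grid$eye_rate <- 5
  grid$sq_score <- 4L; grid$error_rate <- 0.1
  tab <- study_table(grid)
  cc <- compare_conditions(tab, "C")
  expect_equal(cc$test$df, 12)  # 7 + 7 stage means, pooled
  expect_length(cc$stage_deltas, 7)
  ident <- tab; ident$C <- 0.5
  cc0 <- compare_conditions(study_table(ident), "C")
  expect_equal(cc0$test$t, 0)
  expect_false(cc0$test$significant)
})

test_that("error rates count timeouts as mistakes", {
  resp <- data.frame(stage = 1:3, correct = c(30, 20, 0),
                     incorrect = c(0, 3, 0), timeout = c(0, 2, 0))
  out <- error_rate_summary(resp)
  expect_equal(out$error_rate[1], 0)
  expect_equal(out$error_rate[2], 0.2)
  expect_true(is.na(out$error_rate[3]))
  expect_true(out$undefined[3])
  expect_error(error_rate_summary(data.frame(stage = 1, correct = -1,
                                             incorrect = 0, timeout = 0)),
               "non-negative")

  # binomial recovery at p = 0.15
  set.seed(12)
  for (i in 1:5) {
    err <- rbinom(1, 100, 0.15)
    est <- error_rate_summary(data.frame(stage = 1, correct = 100 - err,
                                         incorrect = err, timeout = 0))
    ci <- 0.15 + c(-1, 1) * 1.96 * sqrt(0.15 * 0.85 / 100)
    expect_gte(est$error_rate, ci[1] - 1e-9)
    expect_lte(est$error_rate, ci[2] + 1e-9)
  }
})
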