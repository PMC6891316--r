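test_that("configuration validation catches bad schedules", {
  expect_error(sim_config(coupling_schedule = list(
    normal = rep(1.0, 7), mrm = rep(0.2, 7))), "\\[0, 1\\)")
  expect_error(sim_config(eye_rate_schedule = list(
    normal = rep(-1, 7), mrm = rep(1, 7))), ">= 0")
  expect_error(sim_config(error_rate_schedule = rep(2, 7)), "\\[0, 1\\]")
  expect_error(sim_config(band_power_schedule = list(
    normal = list(theta = 1:3, alpha = rep(1, 7), beta = rep(1, 7)),
    mrm = list(theta = rep(1, 7), alpha = rep(1, 7), beta = rep(1, 7)))),
    "per stage")
  cfg <- sim_config()
  expect_equal(cfg$n_subjects, 12L)
  expect_equal(cfg$stages, 7L)
  expect_equal(cfg$fs, 1000)
  expect_equal(cfg$epoch_seconds, 180)
})

test_that("identical seed and config give bit-identical epochs", {
  cfg <- tiny_cfg(seed = 21)
  a <- simulate_epoch(cfg, 2, "mrm", 3)
  b <- simulate_epoch(cfg, 2, "mrm", 3)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$events, b$events)
  c_ <- simulate_epoch(tiny_cfg(seed = 22), 2, "mrm", 3)
  expect_false(identical(a$recording$samples, c_$recording$samples))
  # the generator restores the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulate_epoch(cfg, 1, "normal", 1))
  expect_identical(rnorm(3), before)
})

test_that("study has the full crossed design and clipped SQ scores", {
  cfg <- sim_config(n_subjects = 12, stages = 7, fs = 128,
                    epoch_seconds = 2.6, seed = 2,
                    sq_schedule = list(normal = c(2, 3, 4, 5, 6, 7, 7),
                                       mrm = c(2, 3, 3, 4, 4, 5, 5)))
  st <- simulate_study(cfg, keep_recordings = FALSE)
  expect_equal(nrow(st$meta), 12 * 2 * 7)
  expect_true(all(st$meta$sq_score >= 1 & st$meta$sq_score <= 7))
  # errors only recorded in the MRM condition
  expect_true(all(is.na(st$meta$n_errors[st$meta$condition == "normal"])))
  expect_true(all(!is.na(st$meta$n_errors[st$meta$condition == "mrm"])))
})

test_that("zero eye rate gives an empty ground-truth list", {
  cfg <- sim_config(n_subjects = 1, stages = 1, fs = 128, epoch_seconds = 10,
                    seed = 4, eye_rate_schedule = list(normal = 0, mrm = 0))
  ep <- simulate_epoch(cfg, 1, "normal", 1)
  expect_equal(nrow(ep$events), 0L)
})

test_that("uncoupled channels have near-zero theta correlations", {
  for (s in 1:3) {
    cfg <- sim_config(n_subjects = 1, stages = 1, fs = 128,
                      epoch_seconds = 180, seed = s,
                      coupling_schedule = list(normal = 0, mrm = 0),
                      eye_rate_schedule = list(normal = 0, mrm = 0))
    rec <- simulate_epoch(cfg, 1, "normal", 1)$recording
    theta <- extract_band(wpd_decompose(rec), "theta")
    r <- correlation_matrix(theta)$r
    expect_lt(max(abs(r[upper.tri(r)])), 0.1)
  }
})

test_that("rising coupling schedules raise empirical theta correlations", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_subjects = 1, stages = 5, fs = 128,
                      epoch_seconds = 10, seed = 100 + s,
                      coupling_schedule = list(
                        normal = seq(0.1, 0.7, length.out = 5),
                        mrm = seq(0.1, 0.4, length.out = 5)),
                      eye_rate_schedule = list(normal = rep(0, 5),
                                               mrm = rep(0, 5)),
                      sq_schedule = list(normal = rep(4, 5), mrm = rep(4, 5)),
                      error_rate_schedule = rep(0.1, 5))
    mean_r <- vapply(1:5, function(stg) {
      rec <- simulate_epoch(cfg, 1, "normal", stg)$recording
      theta <- extract_band(wpd_decompose(rec), "theta")
      r <- correlation_matrix(theta)$r
      mean(r[upper.tri(r)])
    }, 0)
    rho <- cor(1:5, mean_r, method = "spearman")
    if (rho > 0) hits <- hits + 1L
  }
  expect_gt(hits, n_seeds / 2)
})

test_that("injected band-power multipliers are recoverable", {
  cfg <- sim_config(n_subjects = 1, stages = 7, fs = 128,
                    epoch_seconds = 180, seed = 31,
                    eye_rate_schedule = list(normal = rep(0, 7),
                                             mrm = rep(0, 7)),
                    noise_sd = 0.5)
  pw <- function(stage) {
    rec <- simulate_epoch(cfg, 1, "normal", stage)$recording
    bs <- wpd_decompose(rec)
    vapply(c("theta", "alpha", "beta"),
           function(b) band_power(extract_band(bs, b)), 0)
  }
  p1 <- pw(1); p7 <- pw(7)
  sched <- cfg$band_power_schedule$normal
  for (b in c("theta", "alpha", "beta")) {
    injected <- sched[[b]][7] / sched[[b]][1]
    recovered <- p7[b] / p1[b]
    expect_lt(abs(recovered - injected) / injected, 0.15)
  }
})

test_that("study export writes readable epochs and metadata", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_subjects = 2, stages = 2, fs = 128, epoch_seconds = 3,
                    seed = 8)
  st <- simulate_study(cfg, keep_recordings = TRUE, out_dir = dir)
  expect_true(file.exists(file.path(dir, "study_meta.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_recording(file.path(dir, "S02_mrm_2.csv"))
  expect_equal(back$samples, st$epochs[["S02_mrm_2"]]$recording$samples,
               tolerance = 1e-12)
  expect_identical(back$condition, "mrm")
})
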