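#' Two-tailed t test between two samples
#'
#' Thin, design-explicit wrapper around \code{stats::t.test} returning the
#' statistic, degrees of freedom, two-tailed p value and the matching
#' critical value.  The default design is the independent pooled-variance
#' test (df = n_a + n_b - 2), which is the degrees-of-freedom convention the
#' stage-mean and condition comparisons use throughout the pipeline; Welch
#' and paired designs are available.
#'
#' Degenerate inputs are resolved rather than raised: two samples with zero
#' pooled variance and equal means give t = 0, p = 1; zero variance with
#' unequal means is returned as a flagged infinite-t result.
#'
#' @param sample_a,sample_b Numeric vectors (>= 2 values each; equal lengths
#'   for the paired design).
#' @param design \code{"independent_pooled"}, \code{"independent_welch"} or
#'   \code{"paired"}.
#' @param alpha Two-tailed significance level (default 0.05).
#' @return A \code{fatigue_ttest} list: \code{t}, \code{df}, \code{p},
#'   \code{t_crit}, \code{significant}, \code{design}, \code{degenerate}.
#' @export
t_test <- function(sample_a, sample_b,
                   design = c("independent_pooled", "independent_welch",
                              "paired"),
                   alpha = 0.05) {
  design <- match.arg(design)
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each sample needs at least 2 values", call. = FALSE)
  if (design == "paired" && length(sample_a) != length(sample_b))
    stop("paired design requires equal sample lengths", call. = FALSE)
  degenerate <- FALSE
  novar <- switch(design,
    paired = stats::var(sample_a - sample_b) == 0,
    stats::var(sample_a) == 0 && stats::var(sample_b) == 0)
  if (novar) {
    delta <- mean(sample_a) - mean(sample_b)
    df <- switch(design, paired = length(sample_a) - 1,
                 length(sample_a) + length(sample_b) - 2)
    if (delta == 0) {
      t <- 0; p <- 1
    } else {
      t <- sign(delta) * Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    ht <- switch(design,
      independent_pooled = stats::t.test(sample_a, sample_b,
                                         var.equal = TRUE),
      independent_welch = stats::t.test(sample_a, sample_b,
                                        var.equal = FALSE),
      paired = stats::t.test(sample_a, sample_b, paired = TRUE))
    t <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
  }
  structure(list(t = t, df = df, p = p,
                 t_crit = critical_t(alpha, df),
                 significant = p < alpha, design = design, alpha = alpha,
                 degenerate = degenerate),
            class = "fatigue_ttest")
}

#' @export
print.fatigue_ttest <- function(x, ...) {
  cat(sprintf("t = %.3f, df = %.4g, p = %.4f (%s, alpha = %g): %s%s\n",
              x$t, x$df, x$p, x$design, x$alpha,
              if (x$significant) "significant" else "not significant",
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Two-tailed critical value of the t distribution
#'
#' The (1 - alpha/2) quantile of the t distribution: e.g. alpha = 0.05 with
#' df = 18 gives 2.101.
#'
#' @param alpha Two-tailed significance level in (0, 1).
#' @param df Degrees of freedom (>= 1; need not be integer).
#' @return Scalar critical value.
#' @export
critical_t <- function(alpha, df) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(df) || df < 1)
    stop("df must be >= 1", call. = FALSE)
  stats::qt(1 - alpha / 2, df)
}

#' Per-stage summary and monotonic trend of a study-table column
#'
#' Means and SDs over subjects per stage, plus a Spearman rank correlation of
#' stage against value as the monotone-trend statistic.
#'
#' @param table A \code{study_table}.
#' @param column Column name (\code{"C"}, \code{"G"}, \code{"power_ratio"},
#'   \code{"eye_rate"}, \code{"sq_score"}, \code{"error_rate"}).
#' @param condition \code{"normal"} or \code{"mrm"}.
#' @return List with \code{stage_means}, \code{stage_sds} (named by stage),
#'   \code{rho} (Spearman, of per-stage means; 0 and flagged when
#'   tie-degenerate) and \code{tie_degenerate}.
#' @export
stage_trend <- function(table, column, condition) {
  stopifnot(inherits(table, "study_table"))
  sub <- table[table$condition == condition, ]
  if (nrow(sub) == 0) stop("condition not present in table", call. = FALSE)
  stages <- seq(min(table$stage), max(table$stage))
  gaps <- setdiff(stages, unique(sub$stage))
  if (length(gaps))
    stop("missing stage(s) for ", condition, ": ",
         paste(gaps, collapse = ", "), call. = FALSE)
  vals <- sub[[column]]
  mu <- tapply(vals, sub$stage, mean, na.rm = TRUE)
  sd_ <- tapply(vals, sub$stage, stats::sd, na.rm = TRUE)
  if (stats::sd(mu) == 0) {
    rho <- 0; tie <- TRUE
  } else {
    rho <- stats::cor(as.numeric(names(mu)), as.numeric(mu),
                      method = "spearman")
    tie <- FALSE
  }
  list(stage_means = mu, stage_sds = sd_, rho = rho, tie_degenerate = tie)
}

#' Compare the two driving conditions on a study-table column
#'
#' The default comparison follows the stage-mean design: the 7 per-stage
#' means of each condition form the two samples of an independent
#' pooled-variance t test (df = 12 for 7 + 7 stages).
#'
#' @param table A \code{study_table}.
#' @param column Column to compare.
#' @param design t-test design (see \code{\link{t_test}}).
#' @param alpha Significance level.
#' @return List with \code{test} (a \code{fatigue_ttest}) and
#'   \code{stage_deltas} (per-stage normal-minus-MRM differences of means).
#' @export
compare_conditions <- function(table, column,
                               design = "independent_pooled", alpha = 0.05) {
  stopifnot(inherits(table, "study_table"))
  for (cond in c("normal", "mrm"))
    if (!cond %in% table$condition)
      stop("condition '", cond, "' not present", call. = FALSE)
  mu <- function(cond) {
    sub <- table[table$condition == cond, ]
    tapply(sub[[column]], sub$stage, mean, na.rm = TRUE)
  }
  a <- mu("normal"); b <- mu("mrm")
  common <- intersect(names(a), names(b))
  a <- a[common]; b <- b[common]
  list(test = t_test(as.numeric(a), as.numeric(b), design = design,
                     alpha = alpha),
       stage_deltas = a - b)
}

#' Per-stage response error proportions
#'
#' Errors are incorrect answers plus timeouts (a response not completed
#' within the 5 s limit counts as a mistake).
#'
#' @param responses Data.frame with columns \code{stage}, \code{correct},
#'   \code{incorrect}, \code{timeout} (counts).
#' @return Data.frame with \code{stage}, \code{total}, \code{error_rate}
#'   (NA and flagged via the \code{undefined} column when a stage has no
#'   trials).
#' @export
error_rate_summary <- function(responses) {
  req <- c("stage", "correct", "incorrect", "timeout")
  miss <- setdiff(req, names(responses))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  cnt <- responses[, c("correct", "incorrect", "timeout")]
  if (any(cnt < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- rowSums(cnt)
  data.frame(stage = responses$stage, total = total,
             error_rate = ifelse(total > 0,
                                 (responses$incorrect + responses$timeout) /
                                   total, NA_real_),
             undefined = total == 0)
}
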