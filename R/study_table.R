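#' Assemble and validate a study table
#'
#' The study table is the pipeline's aggregated output: one row per
#' (subject, condition, stage) with the mean clustering coefficient \code{C},
#' global efficiency \code{G}, spectral fatigue ratio beta/(theta+alpha),
#' lateral eye-movement rate (events/min), subjective fatigue score (1-7,
#' Samn-Perelli scale) and response error rate.
#'
#' @param df A data.frame with columns \code{subject}, \code{condition},
#'   \code{stage}, \code{C}, \code{G}, \code{power_ratio}, \code{eye_rate},
#'   \code{sq_score}, \code{error_rate}.
#' @return The validated data.frame with class \code{study_table}.
#' @export
study_table <- function(df) {
  req <- c("subject", "condition", "stage", "C", "G", "power_ratio",
           "eye_rate", "sq_score", "error_rate")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("study table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[, req]
  bad_cond <- setdiff(unique(df$condition), c("normal", "mrm"))
  if (length(bad_cond))
    stop("unknown condition value(s): ", paste(bad_cond, collapse = ", "),
         call. = FALSE)
  df$stage <- as.integer(df$stage)
  if (any(df$stage < 1L | df$stage > 7L))
    stop("stage values must be in 1..7", call. = FALSE)
  sq <- df$sq_score[!is.na(df$sq_score)]
  if (any(sq != round(sq) | sq < 1 | sq > 7))
    stop("sq_score values must be integers in 1..7", call. = FALSE)
  for (col in c("C", "G", "power_ratio", "eye_rate", "error_rate"))
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop(col, " must be non-negative", call. = FALSE)
  if (any(df$error_rate > 1, na.rm = TRUE))
    stop("error_rate must lie in [0,1]", call. = FALSE)
  key <- paste(df$subject, df$condition, df$stage)
  if (anyDuplicated(key))
    stop("duplicate (subject, condition, stage) rows", call. = FALSE)
  class(df) <- c("study_table", "data.frame")
  df
}

#' Write a study table as CSV
#' @param table A \code{study_table}.
#' @param path Destination path.
#' @export
write_study_table <- function(table, path) {
  stopifnot(inherits(table, "study_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a study table from CSV
#' @param path CSV path written by \code{\link{write_study_table}}.
#' @return A validated \code{study_table}.
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  study_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Check a study table for missing design cells
#'
#' Reports which (subject, condition, stage) combinations of the full
#' crossed design are absent.
#'
#' @param table A \code{study_table}.
#' @param stages Expected stages (default 1:7).
#' @param conditions Expected conditions.
#' @return A data.frame of missing cells (zero rows when complete).
#' @export
study_table_gaps <- function(table, stages = 1:7,
                             conditions = c("normal", "mrm")) {
  full <- expand.grid(subject = unique(table$subject),
                      condition = conditions, stage = stages,
                      stringsAsFactors = FALSE)
  have <- paste(table$subject, table$condition, table$stage)
  full[!paste(full$subject, full$condition, full$stage) %in% have, ,
       drop = FALSE]
}
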