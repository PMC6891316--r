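#' Study channel montage
#'
#' The 14 channels of the driving study, placed per the international 10-10
#' system.  F3/F4 carry the lateral eye-movement signature; P3/P4 are the
#' default channels for the spectral fatigue ratio.
#' @export
study_channels <- function() {
  c("F3", "F4", "F7", "F8", "FT7", "FT8", "C3", "C4",
    "TP7", "TP8", "P3", "P4", "O1", "O2")
}

#' Construct a multichannel EEG recording
#'
#' The canonical container for one measurement epoch: a channels x time
#' matrix in microvolts, its sampling rate, and the study coordinates
#' (subject, driving condition, stage).
#'
#' @param samples Numeric channels x time matrix (microvolts).
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector, one unique label per row of
#'   \code{samples}; defaults to the row names.
#' @param subject_id Subject identifier.
#' @param condition \code{"normal"} or \code{"mrm"} (man-machine response
#'   mode), or \code{NA} when not applicable.
#' @param stage Driving stage, integer 1-7, or \code{NA}.
#' @return An object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(samples, fs, channel_labels = rownames(samples),
                          subject_id = NA_character_,
                          condition = NA_character_, stage = NA_integer_) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || anyNA(samples))
    stop("samples must be a numeric matrix without missing values",
         call. = FALSE)
  if (ncol(samples) == 0)
    stop("recording has zero samples", call. = FALSE)
  if (is.null(channel_labels))
    stop("channel labels are required", call. = FALSE)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples))
    stop("found ", length(channel_labels), " channel labels for ",
         nrow(samples), " sample rows", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]),
               collapse = ", "), call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  if (!is.na(condition) && !condition %in% c("normal", "mrm"))
    stop("condition must be 'normal' or 'mrm'", call. = FALSE)
  stage <- as.integer(stage)
  if (!is.na(stage) && (stage < 1L || stage > 7L))
    stop("stage must be in 1..7", call. = FALSE)
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs, channel_labels = channel_labels,
                 subject_id = as.character(subject_id),
                 condition = condition, stage = stage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "EEG recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat(sprintf("  subject %s, condition %s, stage %s\n",
              x$subject_id, x$condition, x$stage))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An \code{eeg_recording}.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$fs

.sidecar_path <- function(path) paste0(sub("\\.[^.]+$", "", path), ".json")

#' Read an EEG epoch from disk
#'
#' CSV epochs hold one row per channel with the label in the first column;
#' sampling rate and study coordinates live in a JSON sidecar with the same
#' basename.  EDF epochs are standard 16-bit European Data Format files with
#' study coordinates encoded in the recording-id header field.
#'
#' @param path File path.
#' @param format \code{"csv"} or \code{"edf"}; inferred from the extension by
#'   default.
#' @return An \code{eeg_recording}.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "csv") .read_recording_csv(path) else .read_edf(path)
}

#' Write an EEG epoch to disk
#'
#' @param rec An \code{eeg_recording}.
#' @param path Destination path.
#' @param format \code{"csv"} (exact text round trip) or \code{"edf"}
#'   (16-bit quantization); inferred from the extension by default.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "csv") .write_recording_csv(rec, path) else .write_edf(rec, path)
  invisible(path)
}

.write_recording_csv <- function(rec, path) {
  df <- data.frame(channel = rec$channel_labels,
                   rec$samples, check.names = FALSE)
  colnames(df) <- c("channel", paste0("s", seq_len(ncol(rec$samples))))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = rec$subject_id, condition = rec$condition,
               stage = rec$stage, fs = rec$fs)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
}

.read_recording_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("CSV has no sample columns", call. = FALSE)
  labels <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  dimnames(mat) <- NULL
  if (!is.numeric(mat) || anyNA(mat))
    stop("non-numeric samples in ", path, call. = FALSE)
  sidecar <- .sidecar_path(path)
  if (!file.exists(sidecar))
    stop("missing metadata sidecar: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  eeg_recording(mat, fs = as.numeric(meta$fs), channel_labels = labels,
                subject_id = if (is.null(meta$subject_id)) NA else meta$subject_id,
                condition = if (is.null(meta$condition)) NA else meta$condition,
                stage = if (is.null(meta$stage)) NA else meta$stage)
}

# --- EDF (European Data Format), 16-bit integers, little endian ------------
# One data record holding the whole epoch; physical range symmetric about 0,
# sized to the data.  Study coordinates ride in the recording-id field.

.edf_pad <- function(s, width) formatC(substr(s, 1, width), width = width,
                                       flag = "-")

.write_edf <- function(rec, path) {
  ns <- nrow(rec$samples)
  n <- ncol(rec$samples)
  dur <- n / rec$fs
  pmax_ <- max(1e-6, max(abs(rec$samples))) * 1.0000001
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(paste0("subject=", rec$subject_id), 80),
    .edf_pad(paste("condition", rec$condition, "stage", rec$stage, "fs",
                   format(rec$fs)), 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(format(256 + ns * 256), 8),
    .edf_pad("", 44),
    .edf_pad("1", 8),                       # one data record
    .edf_pad(format(dur, digits = 8), 8),
    .edf_pad(format(ns), 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, .edf_pad, "", width), collapse = ""),
              con, eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("AgAgCl electrode", ns), 80)
  field(rep("uV", ns), 8)
  field(rep(format(-pmax_, digits = 7), ns), 8)
  field(rep(format(pmax_, digits = 7), ns), 8)
  field(rep(format(dig_min), ns), 8)
  field(rep(format(dig_max), ns), 8)
  field(rep("", ns), 80)
  field(rep(format(n), ns), 8)
  scale <- (dig_max - dig_min) / (2 * pmax_)
  for (i in seq_len(ns)) {
    dig <- round((rec$samples[i, ] + pmax_) * scale) + dig_min
    dig <- as.integer(pmin(pmax(dig, dig_min), dig_max))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                    # version
  pat <- rd(80)
  recid <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fields(16)
  fields(80); fields(8)
  pmin_ <- as.numeric(fields(8)); pmax_ <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  mat <- matrix(0, ns, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
      phys <- pmin_[i] + (dig - dmin[i]) * (pmax_[i] - pmin_[i]) /
        (dmax[i] - dmin[i])
      mat[i, (r - 1) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  fs <- spr[1] / (dur / 1)
  meta <- .parse_edf_recid(recid)
  subject <- sub("^subject=", "", pat)
  eeg_recording(mat, fs = if (!is.na(meta$fs)) meta$fs else fs,
                channel_labels = labels,
                subject_id = if (nzchar(subject)) subject else NA,
                condition = meta$condition, stage = meta$stage)
}

.parse_edf_recid <- function(recid) {
  toks <- strsplit(recid, "\\s+")[[1]]
  grab <- function(key) {
    i <- match(key, toks)
    if (is.na(i) || i == length(toks)) NA_character_ else toks[i + 1]
  }
  cond <- grab("condition")
  list(condition = if (is.na(cond) || cond == "NA") NA_character_ else cond,
       stage = suppressWarnings(as.integer(grab("stage"))),
       fs = suppressWarnings(as.numeric(grab("fs"))))
}

#' EDF amplitude quantization step for a recording
#'
#' The resolution at which \code{\link{write_recording}} stores samples in
#' EDF: physical range over the 16-bit digital range.
#' @param rec An \code{eeg_recording}.
#' @return Step size in microvolts.
#' @export
edf_quantization_step <- function(rec) {
  pmax_ <- max(1e-6, max(abs(rec$samples))) * 1.0000001
  2 * pmax_ / 65535
}
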