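#' Relative power spectrum fatigue ratio beta/(theta + alpha)
#'
#' The spectral fatigue index: the ratio of beta band power to the sum of
#' theta and alpha band powers, computed from the wavelet-packet band
#' reconstructions so the network analysis and the ratio share a single band
#' definition.  Vigilance loss raises theta/alpha and lowers beta, so the
#' ratio falls as fatigue deepens.
#'
#' @param bs A \code{band_set} from \code{\link{wpd_decompose}}.
#' @param channels Channel subset for the summary ratio (default P3 and P4,
#'   the posterior sites where the effect is most visible); intersected with
#'   the available channels must be non-empty.
#' @return A \code{power_ratio_result}: \code{per_channel} (named ratio
#'   vector, NA where theta+alpha power is zero), \code{selected} (mean over
#'   the subset), \code{band_powers} (3 x channels matrix, microvolts
#'   squared), \code{undefined_channels}.
#' @export
power_ratio <- function(bs, channels = c("P3", "P4")) {
  stopifnot(inherits(bs, "band_set"))
  labs <- bs$channel_labels
  miss <- setdiff(channels, labs)
  if (length(miss))
    stop("channel(s) not in recording: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- bs$n_samples
  bp <- vapply(c("theta", "alpha", "beta"), function(b) {
    keep <- .band_nodes(bs, band_definitions()[[b]])
    colSums(bs$node_energies[keep, , drop = FALSE]) / m
  }, numeric(length(labs)))
  bp <- t(bp)                      # band x channel
  colnames(bp) <- labs
  denom <- bp["theta", ] + bp["alpha", ]
  ratio <- ifelse(denom > 0, bp["beta", ] / denom, NA_real_)
  names(ratio) <- labs
  structure(list(per_channel = ratio,
                 selected = mean(ratio[channels], na.rm = FALSE),
                 channels = channels,
                 band_powers = bp,
                 undefined_channels = labs[is.na(ratio)]),
            class = "power_ratio_result")
}

#' @export
print.power_ratio_result <- function(x, ...) {
  cat(sprintf("beta/(theta+alpha) over {%s}: %.4f\n",
              paste(x$channels, collapse = ", "), x$selected))
  if (length(x$undefined_channels))
    cat("  undefined (zero theta+alpha power):",
        paste(x$undefined_channels, collapse = ", "), "\n")
  invisible(x)
}

#' Generic band-combination power ratio
#'
#' Ratio of summed band powers, e.g. \code{band_ratio(bs, "theta", "beta")}
#' for the theta/beta index.  Band powers come from wavelet-packet node
#' energies as in \code{\link{power_ratio}}.
#'
#' @param bs A \code{band_set}.
#' @param numerator,denominator Character vectors of band names.
#' @param channels Channel subset (default all).
#' @return Scalar ratio (NA when the denominator power is zero).
#' @export
band_ratio <- function(bs, numerator, denominator,
                       channels = bs$channel_labels) {
  stopifnot(inherits(bs, "band_set"))
  pw <- function(bands) {
    sum(vapply(bands, function(b) {
      keep <- .band_nodes(bs, band_definitions()[[b]])
      mean(colSums(bs$node_energies[keep, channels, drop = FALSE]) /
             bs$n_samples)
    }, numeric(1)))
  }
  num <- pw(numerator); den <- pw(denominator)
  if (den == 0) NA_real_ else num / den
}
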