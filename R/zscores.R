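# Robust standardization used throughout the feature set.

#' Modified Z-scores (median/MAD standardization)
#'
#' Computes M_i = 0.6745 (x_i - median) / MAD, with MAD the median of
#' absolute deviations from the median. When the MAD is zero the mean
#' absolute deviation takes its place, M_i = (x_i - median) /
#' (1.253314 x meanAD); if that is also zero all scores are zero.
#' `NA` entries are ignored when computing the location and scale and
#' propagate to the output.
#'
#' @param values Non-empty numeric vector.
#' @return Numeric vector of scores, same length as `values`.
#' @export
modified_z_scores <- function(values) {
  if (length(values) == 0L) stop("modified_z_scores: empty input")
  obs <- values[!is.na(values)]
  if (length(obs) == 0L) stop("modified_z_scores: all values missing")
  med <- stats::median(obs)
  dev <- values - med
  mad_v <- stats::median(abs(obs - med))
  if (mad_v > 0) return(0.6745 * dev / mad_v)
  mean_ad <- mean(abs(obs - med))
  if (mean_ad > 0) return(dev / (1.253314 * mean_ad))
  ifelse(is.na(values), NA_real_, 0)
}
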