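#' Percentile-based intensity normalization
#'
#' Rescales an MRI channel to `[0, 1]` using robust percentile bounds
#' computed over brain tissue only. Percentiles are taken over strictly
#' positive voxels (zero is the skull-stripped background), every voxel is
#' mapped by `(I - p_low) / (p_high - p_low)` and clamped to `[0, 1]`, and
#' non-positive background voxels map to 0. The percentile estimator is
#' linear interpolation between order statistics (`stats::quantile` type 7).
#'
#' If the percentile range is degenerate (`p_high - p_low < epsilon`) all
#' positive voxels are set to 0 and a warning is raised, so flat channels do
#' not abort batch runs.
#'
#' @param channel 3D (or any-dimensional) numeric array of raw intensities.
#' @param low_percentile lower percentile in `[0, 100)` (default 2).
#' @param high_percentile upper percentile in `(0, 100]` (default 98).
#' @param epsilon tolerance below which the percentile range is considered
#'   degenerate.
#' @return numeric array of the same shape with values in `[0, 1]`.
#' @export
percentile_normalize <- function(channel, low_percentile = 2,
                                 high_percentile = 98, epsilon = 1e-8) {
  if (!(low_percentile >= 0 && low_percentile < high_percentile &&
        high_percentile <= 100))
    stop("percentiles must satisfy 0 <= low < high <= 100")
  pos <- channel > 0
  if (!any(pos)) stop("no strictly positive voxel to normalize on")
  vals <- channel[pos]
  p <- stats::quantile(vals, c(low_percentile, high_percentile) / 100,
                       names = FALSE, type = 7)
  out <- channel
  if (p[2] - p[1] < epsilon) {
    warning("degenerate percentile range; positive voxels set to 0")
    out[] <- 0
    return(out)
  }
  out <- (channel - p[1]) / (p[2] - p[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out[!pos] <- 0
  out
}

#' Min-max intensity normalization (ablation arm)
#'
#' Plain min-max rescaling over strictly positive voxels, used by the
#' ablation harness as the non-robust alternative to
#' [percentile_normalize()]. Background voxels map to 0.
#'
#' @inheritParams percentile_normalize
#' @return numeric array with values in `[0, 1]`.
#' @export
minmax_normalize <- function(channel, epsilon = 1e-8) {
  pos <- channel > 0
  if (!any(pos)) stop("no strictly positive voxel to normalize on")
  vals <- range(channel[pos])
  out <- channel
  if (vals[2] - vals[1] < epsilon) {
    warning("degenerate intensity range; positive voxels set to 0")
    out[] <- 0
    return(out)
  }
  out <- (channel - vals[1]) / (vals[2] - vals[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out[!pos] <- 0
  out
}

#' Normalize every modality of a multi-modal volume
#'
#' @param volume a [multimodal_volume()].
#' @param method `"percentile"` (default) or `"minmax"` (ablation arm).
#' @param low_percentile,high_percentile passed to [percentile_normalize()].
#' @return a [multimodal_volume()] with each channel rescaled to `[0, 1]`.
#' @export
normalize_volume <- function(volume, method = c("percentile", "minmax"),
                             low_percentile = 2, high_percentile = 98) {
  method <- match.arg(method)
  fn <- switch(method,
    percentile = function(a) percentile_normalize(a, low_percentile, high_percentile),
    minmax = minmax_normalize)
  multimodal_volume(lapply(volume$data, fn), spacing = volume$spacing)
}
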