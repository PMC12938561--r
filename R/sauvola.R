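#' Parameters for Sauvola adaptive thresholding
#'
#' @param window odd window side length in pixels (default 15).
#' @param k sensitivity to local contrast (default 0.5).
#' @param R dynamic-range constant. The classical value 128 assumes 8-bit
#'   images; on `[0, 1]`-normalized data the same ratio gives 0.5, which is
#'   the default here.
#' @return list of class `sauvola_params`.
#' @export
sauvola_params <- function(window = 15, k = 0.5, R = 0.5) {
  if (window < 3 || window %% 2 != 1) stop("window must be odd and >= 3")
  if (k < 0) stop("k must be >= 0")
  if (R <= 0) stop("R must be > 0")
  structure(list(window = as.integer(window), k = k, R = R),
            class = "sauvola_params")
}

pad_symmetric <- function(m, h) {
  # symmetric (edge-inclusive) reflection: a b c -> b a | a b c | c b
  n1 <- nrow(m); n2 <- ncol(m)
  if (h >= n1 || h >= n2) stop("window too large for slice")
  i1 <- c(h:1, 1:n1, n1:(n1 - h + 1))
  i2 <- c(h:1, 1:n2, n2:(n2 - h + 1))
  m[i1, i2, drop = FALSE]
}

box_sums <- function(p, w) {
  # sliding w x w window sums of padded matrix p via an integral image
  core <- t(apply(apply(p, 2, cumsum), 1, cumsum))
  ii <- rbind(0, cbind(0, core))
  n1 <- nrow(p) - w + 1L; n2 <- ncol(p) - w + 1L
  ii[(1:n1) + w, (1:n2) + w, drop = FALSE] -
    ii[1:n1, (1:n2) + w, drop = FALSE] -
    ii[(1:n1) + w, 1:n2, drop = FALSE] +
    ii[1:n1, 1:n2, drop = FALSE]
}

#' Sauvola local threshold map
#'
#' Computes, for every pixel of a 2D slice, the adaptive threshold
#' `T(x, y) = m(x, y) * (1 + k * (s(x, y) / R - 1))` where `m` and `s` are
#' the mean and population standard deviation over the `window x window`
#' neighborhood. Borders are handled by symmetric (edge-inclusive)
#' reflection padding.
#'
#' @param slice2d 2D numeric matrix, typically normalized to `[0, 1]`.
#' @param params a [sauvola_params()].
#' @return matrix of thresholds with the shape of `slice2d`.
#' @export
sauvola_threshold_map <- function(slice2d, params = sauvola_params()) {
  if (length(dim(slice2d)) != 2L) stop("non-2D input")
  if (any(!is.finite(slice2d))) stop("non-finite slice values")
  w <- params$window
  h <- (w - 1L) %/% 2L
  p <- pad_symmetric(slice2d, h)
  n <- as.numeric(w)^2
  m <- box_sums(p, w) / n
  msq <- box_sums(p * p, w) / n
  v <- msq - m * m
  v[v < 0] <- 0  # guard tiny negative rounding residue
  s <- sqrt(v)
  m * (1 + params$k * (s / params$R - 1))
}

#' Binarize a slice against a threshold map
#'
#' Applies the strict rule: a pixel is foreground iff its intensity is
#' strictly greater than its local threshold.
#'
#' @param slice2d 2D numeric matrix.
#' @param threshold_map matrix of the same shape.
#' @return logical matrix.
#' @export
binarize <- function(slice2d, threshold_map) {
  if (!identical(dim(slice2d), dim(threshold_map))) stop("shape mismatch")
  slice2d > threshold_map
}

#' Otsu global threshold for one slice (ablation arm)
#'
#' One histogram-based global threshold per slice (256 bins over the slice's
#' intensity range), replacing the Sauvola local map in the ablation
#' harness. Delegates to `EBImage::otsu`.
#'
#' @param slice2d 2D numeric matrix with values in `[0, 1]`.
#' @return logical matrix (`intensity > threshold`).
#' @export
otsu_binarize <- function(slice2d) {
  if (length(dim(slice2d)) != 2L) stop("non-2D input")
  rng <- range(slice2d)
  if (diff(rng) == 0) return(array(FALSE, dim(slice2d)))
  thr <- EBImage::otsu(slice2d, range = rng, levels = 256)
  slice2d > thr
}
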