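PLANES <- c("axial", "coronal", "sagittal")
FUSION_MODES <- c("AND", "MAJORITY", "OR", "SINGLE_AXIAL")

plane_axis <- function(plane) {
  # canonical arrays are (x, y, z): sagittal slices stack along axis 1,
  # coronal along axis 2, axial along axis 3
  switch(plane, sagittal = 1L, coronal = 2L, axial = 3L,
         stop("unknown plane: ", plane))
}

get_slice <- function(arr, axis, i) {
  switch(axis, arr[i, , , drop = TRUE], arr[, i, , drop = TRUE],
         arr[, , i, drop = TRUE])
}

set_slice <- function(arr, axis, i, value) {
  switch(axis,
         { arr[i, , ] <- value; arr },
         { arr[, i, ] <- value; arr },
         { arr[, , i] <- value; arr })
}

#' Per-plane adaptive thresholding and refinement
#'
#' Processes every slice of the given anatomical plane independently:
#' Sauvola threshold map, strict binarization, then per-slice morphological
#' refinement; the refined slices are stacked back into a 3D mask.
#'
#' @param flair 3D numeric array (normalized FLAIR).
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param sauvola a [sauvola_params()].
#' @param morph a [morphology_params()].
#' @param threshold `"sauvola"` (default) or `"otsu"` (ablation arm:
#'   one global threshold per slice).
#' @return 3D logical mask of the same shape.
#' @export
threshold_plane <- function(flair, plane, sauvola = sauvola_params(),
                            morph = morphology_params(),
                            threshold = c("sauvola", "otsu")) {
  threshold <- match.arg(threshold)
  if (length(dim(flair)) != 3L) stop("non-3D input")
  axis <- plane_axis(match.arg(plane, PLANES))
  out <- array(FALSE, dim(flair))
  for (i in seq_len(dim(flair)[axis])) {
    sl <- get_slice(flair, axis, i)
    bin <- if (threshold == "sauvola") {
      binarize(sl, sauvola_threshold_map(sl, sauvola))
    } else {
      otsu_binarize(sl)
    }
    out <- set_slice(out, axis, i, refine_slice(bin, morph))
  }
  out
}

#' Multi-planar mask fusion
#'
#' Combines the per-plane masks voxelwise. `AND` keeps voxels detected in
#' all three planes (the strict default), `MAJORITY` in at least two, `OR`
#' in at least one; `SINGLE_AXIAL` returns the axial mask unchanged.
#'
#' @param masks named list with logical 3D arrays `axial`, `coronal`,
#'   `sagittal` of identical shape.
#' @param strategy one of `"AND"`, `"MAJORITY"`, `"OR"`, `"SINGLE_AXIAL"`.
#' @return 3D logical mask.
#' @export
fuse_masks <- function(masks, strategy = c("AND", "MAJORITY", "OR", "SINGLE_AXIAL")) {
  strategy <- match.arg(strategy)
  stopifnot(all(PLANES %in% names(masks)))
  dms <- lapply(masks[PLANES], dim)
  if (length(unique(vapply(dms, paste, "", collapse = "x"))) != 1L)
    stop("shape mismatch")
  if (strategy == "SINGLE_AXIAL") return(masks$axial)
  votes <- masks$axial + masks$coronal + masks$sagittal
  need <- switch(strategy, AND = 3L, MAJORITY = 2L, OR = 1L)
  array(votes >= need, dim(masks$axial))
}

#' Stage 1: whole-tumor mask from FLAIR
#'
#' Normalizes FLAIR, thresholds and refines every slice of the three
#' anatomical planes, fuses the planar masks, and optionally applies a
#' volumetric cleanup.
#'
#' @param volume a [multimodal_volume()] (raw intensities; FLAIR required).
#' @param config a [pipeline_config()].
#' @return 3D logical whole-tumor mask.
#' @export
run_stage1 <- function(volume, config = pipeline_config()) {
  if (!"FLAIR" %in% volume$modalities) stop("missing FLAIR")
  if (!any(volume$data$FLAIR > 0)) return(array(FALSE, volume$dim))
  flair <- normalize_volume(
    multimodal_volume(volume$data["FLAIR"], volume$spacing),
    method = config$normalization,
    low_percentile = config$low_percentile,
    high_percentile = config$high_percentile)$data$FLAIR
  masks <- lapply(PLANES, function(p)
    threshold_plane(flair, p, config$sauvola,
                    if (config$morphology) config$morph else morphology_params(0, 0, 0),
                    threshold = config$threshold))
  names(masks) <- PLANES
  fused <- fuse_masks(masks, config$fusion)
  postfuse_cleanup(fused, config$morph)
}
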