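#' @useDynLib glioseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

MODALITIES <- c("T1", "T1ce", "T2", "FLAIR")

#' Multi-modal MRI volume container
#'
#' Holds one or more co-registered 3D intensity grids (one per MRI modality)
#' on a shared voxel lattice. All arrays are indexed `(x, y, z)` after
#' canonicalization: axis 1 stacks sagittal slices, axis 2 coronal slices and
#' axis 3 axial slices (RAS order). FLAIR must be present because the
#' whole-tumor mask stage operates on FLAIR alone.
#'
#' @param data named list of 3D numeric arrays; names drawn from
#'   `T1`, `T1ce`, `T2`, `FLAIR`. All arrays must share one shape.
#' @param spacing numeric length-3, voxel size in mm per axis.
#' @return an object of class `multimodal_volume`.
#' @export
multimodal_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.list(data) || is.null(names(data)) || any(!nzchar(names(data))))
    stop("'data' must be a named list of 3D arrays")
  bad <- setdiff(names(data), MODALITIES)
  if (length(bad)) stop("unknown modalities: ", paste(bad, collapse = ", "))
  if (!"FLAIR" %in% names(data)) stop("FLAIR modality is required")
  dims <- lapply(data, dim)
  if (any(vapply(dims, length, 1L) != 3L)) stop("non-3D input")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("inconsistent shapes across modalities")
  if (any(!vapply(data, function(a) all(is.finite(a)), TRUE)))
    stop("non-finite intensities")
  # fixed field order so feature vectors are always (T1, T1ce, T2, FLAIR)
  data <- data[intersect(MODALITIES, names(data))]
  structure(
    list(data = data, spacing = as.numeric(spacing),
         modalities = names(data), dim = dims[[1]]),
    class = "multimodal_volume")
}

#' @export
print.multimodal_volume <- function(x, ...) {
  cat("<multimodal_volume> ", paste(x$dim, collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = " x "), " mm\n",
      " modalities: ", paste(x$modalities, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Subregion label volume
#'
#' Integer label grid using internal codes 0 = background, 1 = necrosis,
#' 2 = edema, 3 = enhancing tumor. The BraTS export dialect maps 3 to 4.
#'
#' @param data 3D integer array with values in `{0, 1, 2, 3}`.
#' @param spacing voxel size in mm per axis.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) stop("non-3D input")
  vals <- unique(as.vector(data))
  if (!all(vals %in% 0:3)) stop("label codes outside {0,1,2,3}")
  structure(list(data = array(as.integer(data), dim(data)),
                 spacing = as.numeric(spacing), dim = dim(data)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  tb <- table(factor(x$data, levels = 0:3,
                     labels = c("background", "necrosis", "edema", "enhancing")))
  cat("<label_volume> ", paste(x$dim, collapse = " x "), " voxels\n", sep = "")
  print(tb)
  invisible(x)
}

canonicalize_nifti <- function(img) {
  # reorient to RAS when the header carries an xform; data without one is
  # taken as already canonical (phantoms are written in RAS)
  ok <- tryCatch({
    RNifti::orientation(img) <- "RAS"
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  img
}

#' Read one modality channel from a NIfTI file
#'
#' The image is reoriented so that array axis 1 stacks sagittal slices,
#' axis 2 coronal and axis 3 axial (RAS voxel order). Images whose header
#' carries no orientation information are assumed already canonical.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @return list with `data` (3D array), `spacing` (mm) — ready to be placed
#'   in a [multimodal_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path)
  img <- canonicalize_nifti(img)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { img <- array(img, d[1:3]); d <- d[1:3] }
  if (length(d) != 3L) stop("non-3D input: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  list(data = array(as.numeric(img), d), spacing = as.numeric(sp))
}

#' Read a full multi-modal volume from per-modality NIfTI files
#'
#' @param paths named character vector, names among `T1`, `T1ce`, `T2`,
#'   `FLAIR`, values file paths.
#' @return a [multimodal_volume()].
#' @export
read_multimodal <- function(paths) {
  chans <- lapply(paths, read_volume)
  sp <- chans[[1]]$spacing
  multimodal_volume(lapply(chans, `[[`, "data"), spacing = sp)
}

#' Write a label volume to NIfTI
#'
#' @param labels a [label_volume()].
#' @param path output file path.
#' @param dialect `"internal"` keeps codes `{0,1,2,3}`; `"brats"` exports
#'   enhancing tumor (internal 3) as code 4, matching the BraTS convention
#'   `{1: NCR, 2: ED, 4: ET}`.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, dialect = c("internal", "brats")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(labels, "label_volume"))
  arr <- labels$data
  if (dialect == "brats") arr[arr == 3L] <- 4L
  img <- RNifti::asNifti(array(as.integer(arr), dim(arr)),
                         pixdim = labels$spacing)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read a label volume from NIfTI
#'
#' @param path NIfTI file with integer codes.
#' @param dialect dialect the file was written in; `"brats"` maps 4 back to
#'   the internal enhancing-tumor code 3.
#' @return a [label_volume()].
#' @export
read_labels <- function(path, dialect = c("internal", "brats")) {
  dialect <- match.arg(dialect)
  ch <- read_volume(path)
  arr <- round(ch$data)
  if (dialect == "brats") {
    if (!all(arr %in% c(0, 1, 2, 4))) stop("label codes outside BraTS dialect {0,1,2,4}")
    arr[arr == 4] <- 3
  }
  label_volume(arr, spacing = ch$spacing)
}

#' Write a binary mask to NIfTI (0/1)
#' @param mask 3D logical array.
#' @param path output path.
#' @param spacing voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)), pixdim = spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write an intensity volume to NIfTI
#' @param arr 3D numeric array.
#' @param path output path.
#' @param spacing voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_channel <- function(arr, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(arr, pixdim = spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}
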