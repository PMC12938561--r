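#' Morphological refinement parameters
#'
#' @param min_component_size components with size less than or equal to this
#'   many pixels are removed from each slice (strict retention `|C| > S_min`).
#' @param opening_radius disk radius of the per-slice opening (pixels).
#' @param closing_radius disk radius of the per-slice closing (pixels).
#' @param cleanup_3d apply an optional volumetric cleanup after fusion
#'   (26-connected small-object removal + spherical closing). Off by default;
#'   the per-slice 2D path is the primary refinement.
#' @param min_component_size_3d volumetric retention threshold used when
#'   `cleanup_3d` is on.
#' @param closing_radius_3d sphere radius of the 3D closing used when
#'   `cleanup_3d` is on.
#' @return list of class `morphology_params`.
#' @export
morphology_params <- function(min_component_size = 64,
                              opening_radius = 2,
                              closing_radius = 3,
                              cleanup_3d = FALSE,
                              min_component_size_3d = 50,
                              closing_radius_3d = 3) {
  stopifnot(min_component_size >= 0, opening_radius >= 0, closing_radius >= 0,
            min_component_size_3d >= 0, closing_radius_3d >= 0)
  structure(list(min_component_size = min_component_size,
                 opening_radius = as.integer(opening_radius),
                 closing_radius = as.integer(closing_radius),
                 cleanup_3d = isTRUE(cleanup_3d),
                 min_component_size_3d = min_component_size_3d,
                 closing_radius_3d = as.integer(closing_radius_3d)),
            class = "morphology_params")
}

disk_offsets <- function(r) {
  # digital disk: integer offsets with dx^2 + dy^2 <= r^2
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

sphere_offsets <- function(r) {
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, , drop = FALSE]
}

neighbor_offsets <- function(ndim, connectivity) {
  if (ndim == 2L) {
    g <- expand.grid(dx = -1:1, dy = -1:1)
    g <- g[!(g$dx == 0 & g$dy == 0), ]
    if (connectivity == 4) g <- g[abs(g$dx) + abs(g$dy) == 1, ]
  } else {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    g <- g[rowSums(abs(g)) > 0, ]
    if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, ]
  }
  # half neighborhood (lexicographically positive) is enough for edges
  g[do.call(order, as.list(g))[seq_len(nrow(g) / 2)], , drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' 8-connectivity in 2D, 26-connectivity in 3D (6/4 selectable). Built on a
#' voxel-adjacency graph and `igraph::components`.
#'
#' @param mask logical matrix or 3D array.
#' @param connectivity 8 or 4 for 2D; 26 or 6 for 3D.
#' @return integer array of the same shape; 0 is background, components are
#'   numbered from 1 in first-voxel order.
#' @export
label_components <- function(mask, connectivity = if (length(dim(mask)) == 2L) 8 else 26) {
  dm <- dim(mask)
  ndim <- length(dm)
  stopifnot(ndim %in% c(2L, 3L))
  out <- array(0L, dm)
  fg <- which(mask)
  n <- length(fg)
  if (n == 0L) return(out)
  id <- array(0L, dm)
  id[fg] <- seq_len(n)
  coord <- arrayInd(fg, dm)
  offs <- neighbor_offsets(ndim, connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coord, 2, as.numeric(offs[r, ]), `+`)
    ok <- rep(TRUE, n)
    for (d in seq_len(ndim)) ok <- ok & nb[, d] >= 1 & nb[, d] <= dm[d]
    if (!any(ok)) next
    lin <- nb[ok, 1]
    if (ndim >= 2) lin <- lin + (nb[ok, 2] - 1) * dm[1]
    if (ndim == 3) lin <- lin + (nb[ok, 3] - 1) * dm[1] * dm[2]
    nbid <- id[lin]
    hit <- nbid > 0L
    from <- c(from, id[fg[ok]][hit])
    to <- c(to, nbid[hit])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  # renumber in first-voxel order for determinism
  first <- match(unique(memb), memb)
  rank <- integer(max(memb))
  rank[memb[sort(first)]] <- seq_along(first)
  out[fg] <- rank[memb]
  out
}

#' Remove small connected components
#'
#' Retains only components whose size is strictly greater than `min_size`
#' pixels/voxels.
#'
#' @param mask logical matrix or 3D array.
#' @param min_size strict retention threshold `|C| > min_size`.
#' @param connectivity passed to [label_components()].
#' @return logical array of the same shape.
#' @export
remove_small_components <- function(mask, min_size,
                                    connectivity = if (length(dim(mask)) == 2L) 8 else 26) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sz <- tabulate(lab[lab > 0L])
  keep <- which(sz > min_size)
  array(lab %in% keep, dim(mask))
}

shift_pad <- function(m, off, fill = FALSE) {
  # shift an array by integer offset vector, filling vacated cells
  dm <- dim(m)
  out <- array(fill, dm)
  src <- dst <- vector("list", length(dm))
  for (d in seq_along(dm)) {
    o <- off[d]
    if (abs(o) >= dm[d]) return(out)
    if (o >= 0) { dst[[d]] <- (1 + o):dm[d]; src[[d]] <- 1:(dm[d] - o) }
    else { dst[[d]] <- 1:(dm[d] + o); src[[d]] <- (1 - o):dm[d] }
  }
  out <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(m), src, list(drop = FALSE))))))
  out
}

erode_se <- function(mask, offs) {
  out <- array(TRUE, dim(mask))
  for (r in seq_len(nrow(offs))) {
    out <- out & shift_pad(mask, -as.numeric(offs[r, ]), fill = FALSE)
    if (!any(out)) break
  }
  out
}

dilate_se <- function(mask, offs) {
  out <- array(FALSE, dim(mask))
  for (r in seq_len(nrow(offs)))
    out <- out | shift_pad(mask, as.numeric(offs[r, ]), fill = FALSE)
  out
}

pad_zeros <- function(mask, r) {
  dm <- dim(mask)
  out <- array(FALSE, dm + 2L * r)
  idx <- lapply(dm, function(n) (r + 1L):(r + n))
  do.call(`[<-`, c(list(out), idx, list(mask)))
}

crop_center <- function(mask, r, dm) {
  idx <- lapply(dm, function(n) (r + 1L):(r + n))
  do.call(`[`, c(list(mask), idx, list(drop = FALSE)))
}

#' Binary opening with a digital disk/sphere
#' @param mask logical matrix (disk) or 3D array (sphere).
#' @param radius structuring-element radius; 0 is the identity.
#' @return logical array.
#' @export
binary_opening <- function(mask, radius) {
  if (radius == 0) return(mask)
  offs <- if (length(dim(mask)) == 2L) disk_offsets(radius) else sphere_offsets(radius)
  dilate_se(erode_se(mask, offs), offs)
}

#' Binary closing with a digital disk/sphere
#'
#' Computed on a zero-padded domain so the result equals the true closing on
#' the infinite grid (extensive: never removes foreground of its input).
#'
#' @inheritParams binary_opening
#' @return logical array.
#' @export
binary_closing <- function(mask, radius) {
  if (radius == 0) return(mask)
  offs <- if (length(dim(mask)) == 2L) disk_offsets(radius) else sphere_offsets(radius)
  p <- pad_zeros(mask, radius)
  crop_center(erode_se(dilate_se(p, offs), offs), radius, dim(mask))
}

#' Per-slice morphological refinement of a binary mask
#'
#' Applies, in order: (i) removal of 8-connected components with at most
#' `min_component_size` pixels, (ii) disk opening, (iii) disk closing.
#'
#' @param mask2d logical matrix.
#' @param params a [morphology_params()].
#' @return logical matrix.
#' @export
refine_slice <- function(mask2d, params = morphology_params()) {
  if (length(dim(mask2d)) != 2L) stop("non-2D input")
  m <- if (params$min_component_size > 0) {
    remove_small_components(mask2d, params$min_component_size, connectivity = 8)
  } else mask2d
  m <- binary_opening(m, params$opening_radius)
  binary_closing(m, params$closing_radius)
}

#' Optional volumetric cleanup after multi-planar fusion
#'
#' When enabled in `params`, removes 26-connected 3D components of at most
#' `min_component_size_3d` voxels and applies a spherical closing. Identity
#' when `cleanup_3d` is off (the default).
#'
#' @param mask 3D logical array.
#' @param params a [morphology_params()].
#' @return 3D logical array.
#' @export
postfuse_cleanup <- function(mask, params = morphology_params()) {
  if (!params$cleanup_3d) return(mask)
  m <- remove_small_components(mask, params$min_component_size_3d, connectivity = 26)
  binary_closing(m, params$closing_radius_3d)
}
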