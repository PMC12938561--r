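check_same_grid <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("shape mismatch")
}

#' Dice similarity coefficient
#'
#' `2 |P intersect G| / (|P| + |G|)`; two empty masks score 1 (perfect
#' agreement convention).
#'
#' @param pred,gt logical arrays on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(pred, gt) {
  check_same_grid(pred, gt)
  np <- sum(pred); ng <- sum(gt)
  if (np + ng == 0) return(1)
  2 * sum(pred & gt) / (np + ng)
}

boundary_voxels <- function(mask) {
  # mask voxels with at least one 6-neighbor outside the mask
  # (the volume edge counts as outside)
  if (!any(mask)) return(matrix(numeric(0), 0, length(dim(mask))))
  interior <- array(TRUE, dim(mask))
  for (d in seq_along(dim(mask))) {
    for (s in c(-1, 1)) {
      off <- rep(0, length(dim(mask))); off[d] <- s
      interior <- interior & shift_pad(mask, off, fill = FALSE)
    }
  }
  arrayInd(which(mask & !interior), dim(mask))
}

directed_pctl_distance <- function(from, to, spacing, prob) {
  # prob-quantile over min distances from each 'from' boundary point to 'to'
  n <- nrow(from)
  mins <- numeric(n)
  chunk <- max(1L, floor(2e6 / max(1L, nrow(to))))
  fs <- sweep(from, 2, spacing, `*`)
  ts <- sweep(to, 2, spacing, `*`)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(rowSums(fs[s:e, , drop = FALSE]^2), rowSums(ts^2), `+`) -
      2 * fs[s:e, , drop = FALSE] %*% t(ts)
    mins[s:e] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  stats::quantile(mins, prob, names = FALSE, type = 7)
}

#' 95th-percentile symmetric surface distance (HD95)
#'
#' Boundary voxels are mask voxels with at least one non-mask 6-neighbor.
#' The metric is the maximum of the two directed 95th-percentile distances
#' between the boundary sets, in millimeters. `NA` when either mask is
#' empty.
#'
#' @param pred,gt logical arrays on the same grid.
#' @param spacing voxel size in mm per axis.
#' @param percentile quantile of the directed distances (default 0.95).
#' @return distance in mm, or `NA` for an empty mask.
#' @export
hd95 <- function(pred, gt, spacing = c(1, 1, 1), percentile = 0.95) {
  check_same_grid(pred, gt)
  if (!any(pred) || !any(gt)) return(NA_real_)
  bp <- boundary_voxels(pred)
  bg <- boundary_voxels(gt)
  max(directed_pctl_distance(bp, bg, spacing, percentile),
      directed_pctl_distance(bg, bp, spacing, percentile))
}

#' Voxelwise recall and precision
#'
#' @param pred,gt logical arrays on the same grid.
#' @return list with `recall`, `precision` (NA when undefined), and the
#'   confusion counts `tp`, `fp`, `fn`.
#' @export
recall_precision <- function(pred, gt) {
  check_same_grid(pred, gt)
  tp <- sum(pred & gt)
  fp <- sum(pred & !gt)
  fn <- sum(!pred & gt)
  list(recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}

#' Evaluate a predicted label volume against ground truth
#'
#' Composes the ET/TC/WT regions of both volumes and scores each with Dice,
#' HD95, recall and precision.
#'
#' @param pred_labels,gt_labels [label_volume()]s (internal dialect) or 3D
#'   integer arrays on the same grid.
#' @param spacing voxel size in mm per axis.
#' @return data.frame with one row per region.
#' @export
evaluate_case <- function(pred_labels, gt_labels, spacing = c(1, 1, 1)) {
  pa <- if (inherits(pred_labels, "label_volume")) pred_labels$data else pred_labels
  ga <- if (inherits(gt_labels, "label_volume")) gt_labels$data else gt_labels
  check_same_grid(pa, ga)
  pr <- compose_regions(pa)
  gr <- compose_regions(ga)
  rows <- lapply(c("WT", "TC", "ET"), function(rg) {
    cc <- recall_precision(pr[[rg]], gr[[rg]])
    data.frame(region = rg,
               dice = dice(pr[[rg]], gr[[rg]]),
               hd95 = hd95(pr[[rg]], gr[[rg]], spacing),
               recall = cc$recall, precision = cc$precision,
               tp = cc$tp, fp = cc$fp, fn = cc$fn)
  })
  do.call(rbind, rows)
}
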