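LABEL_CODES <- c(necrosis = 1L, edema = 2L, enhancing = 3L)

#' Per-cluster mean intensity profiles
#'
#' For every cluster of a partition over masked voxels, the mean normalized
#' intensity per modality and the voxel count.
#'
#' @param partition global partition (assignment over masked voxels).
#' @param raw_features N x B matrix of normalized (not z-scored) modality
#'   intensities for the same masked voxels, columns named by modality.
#' @return data.frame with `cluster`, `n_voxels` and one `mu_<modality>`
#'   column per modality.
#' @export
cluster_profiles <- function(partition, raw_features) {
  if (!length(partition$assignment)) stop("empty partition")
  raw_features <- as.matrix(raw_features)
  cl <- partition$assignment
  ids <- sort(unique(cl))
  mu <- t(vapply(ids, function(k) colMeans(raw_features[cl == k, , drop = FALSE]),
                 numeric(ncol(raw_features))))
  out <- data.frame(cluster = ids, n_voxels = as.integer(tabulate(cl)[ids]))
  colnames(mu) <- paste0("mu_", colnames(raw_features))
  cbind(out, as.data.frame(mu))
}

edema_rank_value <- function(profiles) {
  # edema is ranked by FLAIR hyperintensity, averaged with T2 when present
  if ("mu_T2" %in% names(profiles))
    (profiles$mu_FLAIR + profiles$mu_T2) / 2
  else profiles$mu_FLAIR
}

#' Assign biological labels to anonymous clusters
#'
#' Rank-based radiological assignment: the cluster with the highest mean
#' T1ce intensity is enhancing tumor; among the rest the highest FLAIR
#' (averaged with T2 when present) is edema; the remaining cluster is
#' necrosis. With more than three clusters the three anchors are picked by
#' the same extremal ranks and every other cluster joins the nearest anchor
#' (sigma-normalized Manhattan distance on mean profiles). With two
#' clusters the necrosis class is left empty; a single cluster is labeled
#' edema (whole-lesion fallback).
#'
#' @param profiles output of [cluster_profiles()].
#' @return named integer vector: internal label code per cluster id
#'   (1 = necrosis, 2 = edema, 3 = enhancing tumor).
#' @export
assign_labels <- function(profiles) {
  n <- nrow(profiles)
  if (!n) stop("empty profile list")
  lab <- integer(n)
  if (n == 1L) {
    lab[1] <- LABEL_CODES[["edema"]]
  } else if (n == 2L) {
    et <- which.max(profiles$mu_T1ce)
    lab[et] <- LABEL_CODES[["enhancing"]]
    lab[-et] <- LABEL_CODES[["edema"]]
  } else if (n == 3L) {
    et <- which.max(profiles$mu_T1ce)
    rest <- setdiff(seq_len(n), et)
    ed <- rest[which.max(edema_rank_value(profiles)[rest])]
    lab[et] <- LABEL_CODES[["enhancing"]]
    lab[ed] <- LABEL_CODES[["edema"]]
    lab[setdiff(rest, ed)] <- LABEL_CODES[["necrosis"]]
  } else {
    et <- which.max(profiles$mu_T1ce)
    rest <- setdiff(seq_len(n), et)
    ed <- rest[which.max(profiles$mu_FLAIR[rest])]
    rest2 <- setdiff(rest, ed)
    nec <- rest2[which.min(profiles$mu_T1ce[rest2] + profiles$mu_FLAIR[rest2])]
    anchors <- c(nec, ed, et)
    lab[anchors] <- c(LABEL_CODES[["necrosis"]], LABEL_CODES[["edema"]],
                      LABEL_CODES[["enhancing"]])
    mu <- as.matrix(profiles[, grep("^mu_", names(profiles)), drop = FALSE])
    sg <- apply(mu, 2, pop_sd)
    sg[sg == 0] <- 1
    mz <- sweep(mu, 2, sg, `/`)
    for (i in setdiff(seq_len(n), anchors)) {
      d <- rowSums(abs(sweep(mz[anchors, , drop = FALSE], 2, mz[i, ], `-`)))
      lab[i] <- lab[anchors[which.min(d)]]
    }
  }
  stats::setNames(lab, profiles$cluster)
}

#' Compose evaluation regions from a label volume
#'
#' Enhancing tumor is internal code 3, tumor core combines enhancement and
#' necrosis (codes 1 and 3), and whole tumor all three tumor classes.
#'
#' @param labels a [label_volume()] or 3D integer array with internal codes.
#' @return list of three logical arrays: `ET`, `TC`, `WT`.
#' @export
compose_regions <- function(labels) {
  arr <- if (inherits(labels, "label_volume")) labels$data else labels
  if (!all(arr %in% 0:3)) stop("invalid label codes")
  list(ET = array(arr == 3L, dim(arr)),
       TC = array(arr == 1L | arr == 3L, dim(arr)),
       WT = array(arr != 0L, dim(arr)))
}
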