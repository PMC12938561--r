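#' Affinity-propagation clustering configuration
#'
#' @param patch_size cubic patch side length in voxels (default 5).
#' @param overlap fractional overlap between adjacent patches (default 0.5;
#'   the stride is `floor(patch_size * (1 - overlap))`, rounded down).
#' @param max_iterations message-passing iteration cap (default 200).
#' @param convergence_window stop when the exemplar set is unchanged for
#'   this many consecutive iterations (default 15).
#' @param max_hierarchy_levels depth cap of the exemplar re-clustering
#'   hierarchy (default 3).
#' @param preference_mode `"median_similarity"` (one shared preference, the
#'   median off-diagonal similarity; default) or `"row_mean"` (per-point row
#'   average of the similarity matrix).
#' @param max_pool_exemplars scalability cap on the exemplar pool entering a
#'   re-clustering level: a larger pool is deterministically thinned to this
#'   size (evenly spaced in index order; dropped exemplars merge into their
#'   nearest kept exemplar). Keeps the dense message matrices bounded on
#'   degenerate masks.
#' @return list of class `ap_config`.
#' @export
ap_config <- function(patch_size = 5, overlap = 0.5, max_iterations = 200,
                      convergence_window = 15, max_hierarchy_levels = 3,
                      preference_mode = c("median_similarity", "row_mean"),
                      max_pool_exemplars = 3000) {
  preference_mode <- match.arg(preference_mode)
  stopifnot(patch_size >= 1, overlap >= 0, overlap < 1,
            max_iterations >= 1, convergence_window >= 1,
            max_hierarchy_levels >= 1, max_pool_exemplars >= 2)
  structure(list(patch_size = as.integer(patch_size), overlap = overlap,
                 max_iterations = as.integer(max_iterations),
                 convergence_window = as.integer(convergence_window),
                 max_hierarchy_levels = as.integer(max_hierarchy_levels),
                 preference_mode = preference_mode,
                 max_pool_exemplars = as.integer(max_pool_exemplars)),
            class = "ap_config")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

zscore_columns <- function(f) {
  # population z-score per modality; a constant modality becomes all zeros
  mu <- colMeans(f)
  sg <- apply(f, 2, pop_sd)
  bad <- sg == 0
  if (any(bad)) {
    warning("constant modality over the mask; z-scored to 0: ",
            paste(colnames(f)[bad], collapse = ", "))
    sg[bad] <- 1
  }
  sweep(sweep(f, 2, mu, `-`), 2, sg, `/`)
}

tile_origins <- function(lo, hi, w, stride) {
  span <- hi - lo + 1L
  if (span <= w) return(lo)
  os <- seq.int(lo, hi - w + 1L, by = stride)
  if (os[length(os)] + w - 1L < hi) os <- c(os, hi - w + 1L)
  os
}

#' Extract overlapping feature patches inside the whole-tumor mask
#'
#' Tiles the mask's bounding box with cubic windows (default 5^3 voxels,
#' 50% overlap, stride rounded down). A patch is emitted iff its window
#' contains at least one masked voxel, and holds only the masked voxels.
#' Features are per-voxel modality intensities, z-scored per modality over
#' all masked voxels (population standard deviation).
#'
#' @param volume a [multimodal_volume()] with normalized intensities.
#' @param mask 3D logical whole-tumor mask.
#' @param config an [ap_config()].
#' @return list of class `patch_set` with elements `patches` (list; each has
#'   `patch_id`, `origin`, `index` into the masked-voxel table, `coords`,
#'   `features`), `features` (N x B z-scored matrix over all masked voxels),
#'   `coords` (N x 3), `voxel_index` (linear indices into the volume),
#'   `modalities`, and `n_covering` (patches covering each masked voxel).
#' @export
extract_patches <- function(volume, mask, config = ap_config()) {
  if (!any(mask)) stop("empty mask")
  if (!identical(dim(mask), volume$dim)) stop("mask shape mismatch")
  idx <- which(mask)
  coords <- arrayInd(idx, dim(mask))
  raw <- vapply(volume$data, function(a) a[idx], numeric(length(idx)))
  raw <- matrix(raw, ncol = length(volume$modalities),
                dimnames = list(NULL, volume$modalities))
  feat <- zscore_columns(raw)
  w <- config$patch_size
  stride <- max(1L, as.integer(floor(w * (1 - config$overlap))))
  lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
  ox <- tile_origins(lo[1], hi[1], w, stride)
  oy <- tile_origins(lo[2], hi[2], w, stride)
  oz <- tile_origins(lo[3], hi[3], w, stride)
  # voxel lookup grid: masked-voxel row number at each voxel, 0 elsewhere
  rowno <- array(0L, dim(mask)); rowno[idx] <- seq_along(idx)
  dm <- dim(mask)
  patches <- list(); pid <- 0L
  n_cover <- integer(length(idx))
  for (x0 in ox) for (y0 in oy) for (z0 in oz) {
    xs <- x0:min(x0 + w - 1L, dm[1])
    ys <- y0:min(y0 + w - 1L, dm[2])
    zs <- z0:min(z0 + w - 1L, dm[3])
    rows <- rowno[xs, ys, zs]
    rows <- rows[rows > 0L]
    if (!length(rows)) next
    rows <- sort(rows)
    pid <- pid + 1L
    n_cover[rows] <- n_cover[rows] + 1L
    patches[[pid]] <- list(patch_id = pid, origin = c(x0, y0, z0),
                           index = rows, coords = coords[rows, , drop = FALSE],
                           features = feat[rows, , drop = FALSE])
  }
  structure(list(patches = patches, features = feat, coords = coords,
                 voxel_index = idx, modalities = volume$modalities,
                 raw_features = raw, n_covering = n_cover, dim = dim(mask)),
            class = "patch_set")
}

#' Similarity matrix of a feature set
#'
#' Negative sigma-normalized Manhattan distance:
#' `s(i, k) = -sum_b |A_i^b - A_k^b| / sigma_b`. On z-scored features
#' `sigma_b` is 1; the division is retained so the operation stays correct
#' on raw intensities. Identical points attain the maximal similarity 0,
#' the matrix is symmetric, and the diagonal is 0 until preferences are
#' written to it.
#'
#' @param features L x B numeric matrix.
#' @param sigma optional per-modality scale; defaults to the population
#'   standard deviation of each column. Zero-scale modalities are dropped
#'   with a warning.
#' @return L x L similarity matrix.
#' @export
build_similarity <- function(features, sigma = NULL) {
  features <- as.matrix(features)
  L <- nrow(features)
  if (L < 1) stop("empty feature set")
  if (is.null(sigma)) sigma <- apply(features, 2, pop_sd)
  drop <- sigma == 0
  if (any(drop)) {
    warning("zero-variance modality dropped from similarity: ",
            paste(which(drop), collapse = ", "))
  }
  S <- matrix(0, L, L)
  for (b in which(!drop))
    S <- S - abs(outer(features[, b], features[, b], `-`)) / sigma[b]
  S
}

#' Exemplar preferences
#'
#' `"row_mean"`: per-point preference equal to the average of its similarity
#' row (diagonal included). `"median_similarity"`: one shared preference
#' equal to the median off-diagonal similarity (the default used by the
#' pipeline).
#'
#' @param S similarity matrix (diagonal still 0).
#' @param mode `"median_similarity"` or `"row_mean"`.
#' @return numeric vector of length `L` (shared value recycled).
#' @export
compute_preferences <- function(S, mode = c("median_similarity", "row_mean")) {
  mode <- match.arg(mode)
  L <- nrow(S)
  if (L == 0) stop("empty similarity matrix")
  if (mode == "row_mean") return(rowMeans(S))
  if (L == 1) return(0)
  rep(stats::median(S[row(S) != col(S)]), L)
}

#' Fresh message state for [ap_step()]
#'
#' Messages start at zero; the smoothing buffer is primed with the zero
#' initial messages so the moving average always runs over four entries.
#'
#' @param L number of points.
#' @return list with zero messages, zero-primed history and iteration 0.
#' @export
new_ap_state <- function(L) {
  z <- matrix(0, L, L)
  zp <- list(r = z, a = z)
  list(r = z, a = z, rhat = z, ahat = z,
       history = list(zp, zp, zp), iteration = 0L)
}

#' One round of affinity-propagation message passing
#'
#' Updates responsibilities from the current smoothed availabilities,
#' smooths them as a moving average over the last four iterations (the
#' fresh update plus the three previously retained responsibilities; the
#' buffer is primed with the zero initial messages), then updates
#' availabilities from the smoothed responsibilities and smooths them the
#' same way. The retained (smoothed) messages enter the history, so the
#' smoothing is applied iteratively; it replaces classical damping.
#'
#' @param state message state from `new_ap_state()` or a previous step.
#' @param S similarity matrix with preferences on the diagonal.
#' @return updated state: `r`/`a` are the raw updates, `rhat`/`ahat` the
#'   retained smoothed messages, `history` the ring buffer of at most four
#'   retained message pairs.
#' @export
ap_step <- function(state, S) {
  rraw <- .ap_resp_cpp(S, state$ahat)
  prev <- state$history
  if (length(prev) > 3L) prev <- prev[-seq_len(length(prev) - 3L)]
  rhat <- (Reduce(`+`, lapply(prev, `[[`, "r")) + rraw) / 4
  araw <- .ap_avail_cpp(rhat)
  ahat <- (Reduce(`+`, lapply(prev, `[[`, "a")) + araw) / 4
  if (any(!is.finite(rhat)) || any(!is.finite(ahat)))
    stop("non-finite message at iteration ", state$iteration + 1L)
  history <- c(state$history, list(list(r = rhat, a = ahat)))
  if (length(history) > 4L) history <- history[-1L]
  list(r = rraw, a = araw, rhat = rhat, ahat = ahat,
       history = history, iteration = state$iteration + 1L)
}

#' Select exemplars and assignments from smoothed responsibilities
#'
#' `E*(i) = argmax_k rhat(i, k)` (ties to the lowest index). Points that are
#' their own argmax become exemplars. The argmax map is a functional graph,
#' so every component ends in a cycle; when a cycle has no self-argmax
#' point (mutually pointing pairs deadlock this way on tied preferences),
#' its lowest-index member is promoted to exemplar, which keeps the
#' procedure fully deterministic. Every other point is assigned to its
#' argmax target, re-pointed through one chase step if the target is
#' itself assigned elsewhere, with a final fallback to the most similar
#' exemplar.
#'
#' @param state message state after at least one [ap_step()].
#' @param S similarity matrix (used only for the nearest-exemplar fallback).
#' @return a partition: list with `assignment` (cluster id per point),
#'   `exemplars` (point index per cluster), `n_clusters`, `level`.
#' @export
select_exemplars <- function(state, S) {
  rhat <- state$rhat
  L <- nrow(rhat)
  estar <- vapply(seq_len(L), function(i) which.max(rhat[i, ]), 1L)
  ex <- which(estar == seq_len(L))
  if (!length(ex)) {
    # deadlock: no point elects itself (symmetric ties leave only mutually
    # pointing cycles). Each component of the argmax map ends in a cycle;
    # promote the lowest-index member of every cycle.
    color <- integer(L)  # 0 unseen, 1 on current walk, 2 finished
    for (start in seq_len(L)) {
      if (color[start] != 0L) next
      walk <- integer(0)
      i <- start
      while (color[i] == 0L) {
        color[i] <- 1L
        walk <- c(walk, i)
        i <- estar[i]
      }
      if (color[i] == 1L) {  # found a new cycle along this walk
        cyc <- walk[seq(match(i, walk), length(walk))]
        ex <- c(ex, min(cyc))
      }
      color[walk] <- 2L
    }
    ex <- sort(ex)
  }
  if (!length(ex)) ex <- which.max(diag(rhat))  # unreachable safety net
  target <- integer(L)
  for (i in seq_len(L)) {
    t1 <- estar[i]
    if (i %in% ex) { target[i] <- i; next }
    if (t1 %in% ex) { target[i] <- t1; next }
    t2 <- estar[t1]
    target[i] <- if (t2 %in% ex) t2 else ex[which.max(S[i, ex])]
  }
  exemplars <- sort(unique(c(ex, target[ex])))
  cluster_of <- match(target, exemplars)
  list(assignment = cluster_of, exemplars = exemplars,
       n_clusters = length(exemplars), level = 1L)
}

#' Cluster one feature set by modified affinity propagation
#'
#' Builds the similarity matrix, writes the preference to its diagonal, and
#' iterates message passing with 4-iteration moving-average smoothing until
#' the exemplar set is unchanged for `convergence_window` consecutive
#' iterations or `max_iterations` elapse. Fully deterministic.
#'
#' @param features L x B numeric matrix (typically z-scored).
#' @param config an [ap_config()].
#' @param sigma optional per-modality scale for [build_similarity()].
#' @return a partition (see [select_exemplars()]) with attributes
#'   `iterations` and `converged`.
#' @export
run_affinity_propagation <- function(features, config = ap_config(), sigma = NULL) {
  features <- as.matrix(features)
  L <- nrow(features)
  if (L == 0) stop("empty feature set")
  if (L == 1) {
    return(structure(list(assignment = 1L, exemplars = 1L,
                          n_clusters = 1L, level = 1L),
                     iterations = 0L, converged = TRUE))
  }
  S <- build_similarity(features, sigma)
  p <- compute_preferences(S, config$preference_mode)
  diag(S) <- p
  res <- .ap_run_cpp(S, config$max_iterations, config$convergence_window)
  part <- select_exemplars(list(rhat = res$rhat), S)
  structure(part, iterations = res$iterations, converged = res$converged)
}

global_partition <- function(patch_set, exemplar_rows, level,
                             chain = NULL) {
  # assign every masked voxel to a cluster of the given exemplar set:
  # single-covered voxels inherit their patch chain when available,
  # multi-covered voxels go to the exemplar with maximal similarity
  # (minimal L1 distance in z-scored feature space)
  F <- patch_set$features
  E <- F[exemplar_rows, , drop = FALSE]
  nn <- .l1_nearest_cpp(F, E)
  assignment <- nn$index
  if (!is.null(chain)) {
    single <- patch_set$n_covering == 1L
    ok <- single & !is.na(chain)
    assignment[ok] <- chain[ok]
  }
  # exemplars must sit in their own cluster
  assignment[exemplar_rows] <- seq_along(exemplar_rows)
  list(assignment = as.integer(assignment),
       exemplars = as.integer(exemplar_rows),
       n_clusters = length(exemplar_rows), level = as.integer(level))
}

#' Hierarchical refinement of patch-level partitions
#'
#' Pools the feature vectors of all level-1 exemplars and re-clusters them
#' with the same affinity-propagation procedure, repeating until the
#' exemplar set stabilizes or `max_hierarchy_levels` is reached. At every
#' level a global partition over all masked voxels is formed: voxels
#' covered by a single patch inherit their chain of exemplars; voxels in
#' overlapping patches are assigned to the level's most similar exemplar.
#'
#' @param level1 list of per-patch partitions (aligned with
#'   `patch_set$patches`).
#' @param patch_set the [extract_patches()] output the partitions came from.
#' @param config an [ap_config()].
#' @return list with `candidates` (one global partition per hierarchy
#'   level, shallowest first) and `final` (deepest level).
#' @export
hierarchical_refine <- function(level1, patch_set, config = ap_config()) {
  stopifnot(length(level1) >= 1)
  # voxel -> level-1 exemplar (global row), last patch wins for overlap;
  # only used for single-covered voxels where it is unambiguous
  n <- nrow(patch_set$features)
  vox_ex <- rep(NA_integer_, n)
  ex_rows <- integer(0)
  for (j in seq_along(level1)) {
    p <- patch_set$patches[[j]]
    part <- level1[[j]]
    gex <- p$index[part$exemplars]
    ex_rows <- c(ex_rows, gex)
    vox_ex[p$index] <- gex[part$assignment]
  }
  ex_rows <- sort(unique(ex_rows))
  # map: level-1 exemplar row -> current top exemplar row (chain)
  top_of <- stats::setNames(ex_rows, ex_rows)
  chain_clusters <- function(current) {
    match(unname(top_of[as.character(vox_ex)]), current)
  }
  candidates <- list(
    global_partition(patch_set, ex_rows, level = 1L,
                     chain = chain_clusters(ex_rows)))
  current <- ex_rows
  level <- 1L
  while (level < config$max_hierarchy_levels && length(current) > 1L) {
    if (length(current) > config$max_pool_exemplars) {
      # scalability safeguard: thin the pool deterministically and merge
      # dropped exemplars into their nearest kept exemplar
      keep <- current[unique(round(seq(1, length(current),
                                       length.out = config$max_pool_exemplars)))]
      nn <- .l1_nearest_cpp(patch_set$features[current, , drop = FALSE],
                            patch_set$features[keep, , drop = FALSE])
      thin_map <- stats::setNames(keep[nn$index], current)
      top_of[] <- unname(thin_map[as.character(top_of)])
      current <- keep
    }
    # features are z-scored over the whole masked region, so the modality
    # scale is 1 by construction at every level
    part <- run_affinity_propagation(patch_set$features[current, , drop = FALSE],
                                     config,
                                     sigma = rep(1, ncol(patch_set$features)))
    new_ex <- current[part$exemplars]
    level <- level + 1L
    # follow the chain one level down
    step_map <- stats::setNames(current[part$exemplars[part$assignment]], current)
    top_of[] <- unname(step_map[as.character(top_of)])
    candidates[[level]] <- global_partition(
      patch_set, new_ex, level = level, chain = chain_clusters(new_ex))
    if (identical(new_ex, current)) break
    current <- new_ex
  }
  list(candidates = candidates, final = candidates[[length(candidates)]])
}

#' Partition-quality score (intra/inter validity criterion)
#'
#' `score = inter / (1 + intra)` with `intra` the mean sigma-normalized
#' Manhattan distance from each voxel to its cluster's exemplar, and
#' `inter` the mean pairwise distance between exemplars. Single-cluster
#' partitions score 0 (no separation).
#'
#' @param partition a global partition (assignment + exemplars).
#' @param features N x B feature matrix the partition refers to.
#' @return non-negative real score.
#' @export
levine_nazif_score <- function(partition, features) {
  if (partition$n_clusters < 1) stop("empty partition")
  features <- as.matrix(features)
  E <- features[partition$exemplars, , drop = FALSE]
  dists <- rowSums(abs(features - E[partition$assignment, , drop = FALSE]))
  intra <- mean(dists)
  inter <- .l1_pairwise_mean_cpp(E)
  inter / (1 + intra)
}

#' Select the optimal partition across hierarchy levels
#'
#' Returns the candidate maximizing [levine_nazif_score()]; ties go to the
#' shallowest level.
#'
#' @param candidates list of global partitions, shallowest first.
#' @param features N x B feature matrix.
#' @return the selected partition, with attribute `scores`.
#' @export
select_optimal_partition <- function(candidates, features) {
  if (!length(candidates)) stop("empty candidate list")
  scores <- vapply(candidates, levine_nazif_score, 0, features = features)
  best <- which.max(scores)  # first maximum = shallowest level
  structure(candidates[[best]], scores = scores)
}
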