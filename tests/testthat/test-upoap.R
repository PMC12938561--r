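mk_volume <- function(mask_dim, nmod = 2) {
  set.seed(99)
  mods <- c("T1ce", "FLAIR", "T1", "T2")[seq_len(nmod)]
  d <- lapply(stats::setNames(mods, mods), function(m)
    array(runif(prod(mask_dim), 0.1, 1), mask_dim))
  if (!"FLAIR" %in% names(d)) names(d)[1] <- "FLAIR"
  multimodal_volume(d)
}

test_that("patch tiling matches a brute-force origin enumeration", {
  dm <- c(12, 12, 12)
  vol <- mk_volume(dm)
  mask <- array(FALSE, dm)
  mask[2:11, 2:11, 2:11] <- TRUE   # 10^3 all-true bounding box
  ps <- extract_patches(vol, mask, ap_config())
  # independent origin enumeration: stride 2, final window pinned to the end
  origins <- function(lo, hi) {
    os <- integer(0); o <- lo
    while (o + 4 <= hi) { os <- c(os, o); o <- o + 2 }
    if (os[length(os)] + 4 < hi) os <- c(os, hi - 4)
    os
  }
  os <- origins(2, 11)
  count <- 0
  for (x in os) for (y in os) for (z in os)
    if (any(mask[x:(x + 4), y:(y + 4), z:(z + 4)])) count <- count + 1
  expect_equal(length(ps$patches), count)
  expect_equal(count, length(os)^3)
})

test_that("a single-voxel mask yields one patch with that voxel", {
  dm <- c(12, 12, 12)
  vol <- mk_volume(dm)
  mask <- array(FALSE, dm); mask[6, 7, 8] <- TRUE
  expect_warning(ps <- extract_patches(vol, mask, ap_config()),
                 "constant modality")  # one voxel cannot be z-scored
  expect_equal(length(ps$patches), 1L)
  expect_equal(nrow(ps$patches[[1]]$features), 1L)
  expect_equal(unname(ps$patches[[1]]$coords[1, ]), c(6, 7, 8))
  expect_error(extract_patches(vol, array(FALSE, dm)), "empty mask")
})

test_that("features are z-scored per modality over the masked voxels", {
  dm <- c(10, 10, 10)
  vol <- mk_volume(dm, nmod = 4)
  mask <- array(runif(prod(dm)) < 0.4, dm)
  ps <- extract_patches(vol, mask, ap_config())
  expect_lt(max(abs(colMeans(ps$features))), 1e-8)
  expect_lt(max(abs(apply(ps$features, 2, function(x) mean(x^2)) - 1)), 1e-8)
})

test_that("similarity is the negative scale-normalized Manhattan distance", {
  sig <- c(1, 2, 3, 4)
  f <- rbind(c(0, 0, 0, 0), sig)
  S <- build_similarity(f, sigma = sig)
  expect_equal(S[1, 2], -4)
  expect_equal(S[2, 1], -4)
  expect_equal(unname(diag(S)), c(0, 0))
  # identical vectors attain the maximal similarity 0
  S2 <- build_similarity(rbind(c(1, 2), c(1, 2)), sigma = c(1, 1))
  expect_equal(S2[1, 2], 0)
  # symmetry on random inputs, and agreement with a pairwise-loop oracle
  set.seed(5)
  f <- matrix(rnorm(10 * 4), 10, 4)
  sg <- apply(f, 2, function(x) sqrt(mean((x - mean(x))^2)))
  S <- build_similarity(f)
  expect_equal(S, t(S))
  i <- 3; k <- 8
  expect_equal(S[i, k], -sum(abs(f[i, ] - f[k, ]) / sg), tolerance = 1e-12)
})

test_that("preferences follow the row mean and the shared median rules", {
  S <- matrix(c(0, -2, -2, 0), 2, 2)
  expect_equal(compute_preferences(S, "row_mean"), c(-1, -1))
  S3 <- matrix(-3, 4, 4); diag(S3) <- 0
  expect_equal(compute_preferences(S3, "median_similarity"), rep(-3, 4))
  set.seed(8)
  R <- matrix(rnorm(36), 6, 6); R <- -abs(R + t(R)); diag(R) <- 0
  expect_equal(compute_preferences(R, "row_mean"),
               sapply(1:6, function(i) sum(R[i, ]) / 6))
})

test_that("one message-passing step reproduces the hand-computed 2-point case", {
  # features 0 and 1 in one dimension, sigma = 1, row-mean preferences:
  # S = [[-0.5, -1], [-1, -0.5]]; from the zero state the raw
  # responsibilities are [[0.5, -0.5], [-0.5, 0.5]]; the zero-primed
  # 4-window average quarters them, and every availability term is 0.
  S <- matrix(c(-0.5, -1, -1, -0.5), 2, 2)
  st <- ap_step(new_ap_state(2), S)
  expect_equal(st$r, matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))
  expect_equal(st$rhat, matrix(c(0.125, -0.125, -0.125, 0.125), 2, 2))
  expect_equal(st$a, matrix(0, 2, 2))
  expect_equal(st$ahat, matrix(0, 2, 2))
  expect_equal(st$iteration, 1L)
})

test_that("stationary messages make smoothed and raw coincide", {
  S <- matrix(c(-0.5, -1, -1, -0.5), 2, 2)
  st <- new_ap_state(2)
  for (i in 1:300) st <- ap_step(st, S)  # geometric approach to stationarity
  expect_equal(st$rhat, st$r, tolerance = 1e-8)
  expect_equal(st$ahat, st$a, tolerance = 1e-8)
})

test_that("the smoothing history never exceeds four snapshots", {
  S <- matrix(c(-0.5, -1, -1, -0.5), 2, 2)
  st <- new_ap_state(2)
  for (i in 1:7) {
    st <- ap_step(st, S)
    expect_lte(length(st$history), 4L)
  }
})

test_that("stepping in R reproduces the compiled full run", {
  set.seed(21)
  for (rep in 1:3) {
    b <- make_blobs(rep + 100, n_per = 5)
    S <- build_similarity(b$X, sigma = rep(1, 4))
    diag(S) <- compute_preferences(S)
    res <- glioseg:::.ap_run_cpp(S, 40, 1000)  # fixed iterations, no early stop
    st <- new_ap_state(nrow(S))
    for (i in 1:40) st <- ap_step(st, S)
    expect_equal(st$rhat, res$rhat, tolerance = 1e-10)
    expect_equal(st$ahat, res$ahat, tolerance = 1e-10)
  }
})

test_that("exemplar selection breaks ties toward the lowest index", {
  rhat <- matrix(-5, 6, 6)
  rhat[2, 2] <- 1; rhat[5, 5] <- 1          # two exemplars
  rhat[1, 2] <- 0.5; rhat[1, 5] <- 0.5      # tie for point 1
  S <- matrix(-1, 6, 6)
  part <- select_exemplars(list(rhat = rhat), S)
  expect_true(all(c(2, 5) %in% part$exemplars))
  expect_equal(part$assignment[1], part$assignment[2])  # went to candidate 2
})

test_that("degenerate selections still produce a valid partition", {
  # single point
  p1 <- run_affinity_propagation(matrix(0, 1, 4))
  expect_equal(p1$n_clusters, 1L)
  expect_equal(p1$exemplars, 1L)
  # two identical points collapse to one cluster anchored at the lower index
  p2 <- run_affinity_propagation(rbind(c(1, 1), c(1, 1)), sigma = c(1, 1))
  expect_equal(p2$n_clusters, 1L)
  expect_equal(p2$assignment, c(1L, 1L))
})

test_that("exemplars always belong to their own cluster", {
  for (seed in c(2, 9, 31)) {
    b <- make_blobs(seed)
    part <- run_affinity_propagation(b$X)
    for (j in seq_along(part$exemplars))
      expect_equal(part$assignment[part$exemplars[j]], j)
  }
})

test_that("clustering is deterministic", {
  b <- make_blobs(4)
  p1 <- run_affinity_propagation(b$X)
  p2 <- run_affinity_propagation(b$X)
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(p1$exemplars, p2$exemplars)
})

test_that("well-separated blobs are recovered as distinct clusters", {
  # two tight blobs of three points each
  set.seed(50)
  X <- rbind(matrix(rnorm(12, 0, 0.03), 3, 4),
             matrix(rnorm(12, 0, 0.03), 3, 4) + 2)
  part <- run_affinity_propagation(X, sigma = rep(1, 4))
  expect_equal(part$n_clusters, 2L)
  expect_equal(length(unique(part$assignment[1:3])), 1L)
  expect_equal(length(unique(part$assignment[4:6])), 1L)
  expect_false(part$assignment[1] == part$assignment[4])
})

test_that("hierarchy merges redundant exemplars from separated blobs", {
  b <- make_blobs(17, n_per = 10)
  # six single-blob patches, two per blob -> six level-1 exemplars (medoids)
  idxs <- split(seq_len(30), rep(1:6, each = 5))
  ps <- construct_patch_set(b$X, idxs)
  level1 <- lapply(ps$patches, function(p) {
    med <- which.min(rowSums(as.matrix(dist(p$features, method = "manhattan"))))
    list(assignment = rep(1L, nrow(p$features)), exemplars = unname(med),
         n_clusters = 1L, level = 1L)
  })
  hr <- hierarchical_refine(level1, ps, ap_config())
  expect_equal(hr$candidates[[1]]$n_clusters, 6L)
  ks <- vapply(hr$candidates, `[[`, 1L, "n_clusters")
  expect_true(all(diff(ks) <= 0))                  # non-increasing
  expect_lte(length(hr$candidates), 3L)            # depth cap
  best <- select_optimal_partition(hr$candidates, ps$features)
  expect_equal(best$n_clusters, 3L)
  expect_equal(adjusted_rand(best$assignment, b$labels), 1)
})

test_that("a single level-1 cluster passes through the hierarchy unchanged", {
  set.seed(61)
  X <- matrix(rnorm(20 * 4, 0, 0.01), 20, 4)
  ps <- construct_patch_set(X, list(1:20))
  level1 <- list(run_affinity_propagation(X, sigma = rep(1, 4)))
  if (level1[[1]]$n_clusters == 1L) {
    hr <- hierarchical_refine(level1, ps, ap_config())
    for (cand in hr$candidates) expect_equal(cand$n_clusters, 1L)
  } else skip("level-1 clustering split the blob; covered elsewhere")
})

test_that("the validity score is zero for degenerate partitions and favors structure", {
  # hand-computable 4-point, 2-cluster configuration (1-D features):
  # clusters {0, 1} and {10, 11} with exemplars 0 and 10:
  # intra = (0 + 1 + 0 + 1)/4 = 0.5, inter = 10, score = 10/1.5
  f <- matrix(c(0, 1, 10, 11), 4, 1)
  part <- list(assignment = c(1L, 1L, 2L, 2L), exemplars = c(1L, 3L),
               n_clusters = 2L, level = 1L)
  expect_equal(levine_nazif_score(part, f), 10 / 1.5)
  one <- list(assignment = rep(1L, 4), exemplars = 1L, n_clusters = 1L, level = 1L)
  expect_equal(levine_nazif_score(one, f), 0)
  # identical voxels, one cluster -> 0/1
  expect_equal(levine_nazif_score(one, matrix(0, 4, 1)), 0)
  # 3-blob data: the true 3-cluster partition beats the 1-cluster merge
  b <- make_blobs(23)
  truth <- run_affinity_propagation(b$X)
  merged <- list(assignment = rep(1L, 60), exemplars = truth$exemplars[1],
                 n_clusters = 1L, level = 2L)
  expect_gt(levine_nazif_score(truth, b$X), levine_nazif_score(merged, b$X))
})

test_that("partition selection takes the argmax and prefers shallow ties", {
  f <- matrix(c(0, 1, 10, 11), 4, 1)
  p2 <- list(assignment = c(1L, 1L, 2L, 2L), exemplars = c(1L, 3L),
             n_clusters = 2L, level = 1L)
  p1 <- list(assignment = rep(1L, 4), exemplars = 1L, n_clusters = 1L, level = 2L)
  expect_identical(select_optimal_partition(list(p1), f)$level, 2L)
  got <- select_optimal_partition(list(p1, p2, p1), f)
  expect_identical(got$n_clusters, 2L)
  # equal scores at two levels -> the shallower (earlier) candidate wins
  tie <- select_optimal_partition(list(p2, within(p2, level <- 2L)), f)
  expect_identical(tie$level, 1L)
  expect_error(select_optimal_partition(list(), f), "empty")
})
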