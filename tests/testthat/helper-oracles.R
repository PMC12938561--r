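# Independent brute-force oracles and fixture generators. Everything here is
# written against the declared contracts, not against the package internals.

# ---- percentile oracle: linear interpolation between order statistics ----
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# ---- Sauvola oracle: per-pixel loops with symmetric reflection ----
reflect_index <- function(i, n) {
  if (i < 1) return(1 - i)
  if (i > n) return(2 * n + 1 - i)
  i
}

oracle_sauvola <- function(slice, window, k, R) {
  h <- (window - 1) / 2
  n1 <- nrow(slice); n2 <- ncol(slice)
  ridx <- vapply(seq(1 - h, n1 + h), reflect_index, 1, n = n1)
  cidx <- vapply(seq(1 - h, n2 + h), reflect_index, 1, n = n2)
  padded <- slice[ridx, cidx, drop = FALSE]
  out <- matrix(0, n1, n2)
  for (i in 1:n1) for (j in 1:n2) {
    vals <- padded[i:(i + 2 * h), j:(j + 2 * h)]
    m <- mean(vals)
    s <- sqrt(mean((vals - m)^2))
    out[i, j] <- m * (1 + k * (s / R - 1))
  }
  out
}

# ---- connected components oracle: iterative min-label propagation ----
oracle_label_2d <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  lab <- matrix(0L, n1, n2)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (i in 1:n1) for (j in 1:n2) {
      if (!mask[i, j]) next
      best <- lab[i, j]
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= n1 && jj >= 1 && jj <= n2 && mask[ii, jj])
          best <- min(best, lab[ii, jj])
      }
      if (best < lab[i, j]) { lab[i, j] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  lab
}

oracle_remove_small <- function(mask, min_size) {
  lab <- oracle_label_2d(mask)
  keep <- mask
  for (l in setdiff(unique(as.vector(lab)), 0L))
    if (sum(lab == l) <= min_size) keep[lab == l] <- FALSE
  keep
}

oracle_disk <- function(r) {
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs[offs$di^2 + offs$dj^2 <= r^2, ]
}

oracle_erode <- function(mask, r) {
  if (r == 0) return(mask)
  offs <- oracle_disk(r)
  n1 <- nrow(mask); n2 <- ncol(mask)
  out <- matrix(FALSE, n1, n2)
  for (i in 1:n1) for (j in 1:n2) {
    ok <- TRUE
    for (t in seq_len(nrow(offs))) {
      ii <- i + offs$di[t]; jj <- j + offs$dj[t]
      v <- ii >= 1 && ii <= n1 && jj >= 1 && jj <= n2 && mask[ii, jj]
      if (!v) { ok <- FALSE; break }
    }
    out[i, j] <- ok
  }
  out
}

oracle_dilate <- function(mask, r) {
  if (r == 0) return(mask)
  offs <- oracle_disk(r)
  n1 <- nrow(mask); n2 <- ncol(mask)
  out <- matrix(FALSE, n1, n2)
  for (i in 1:n1) for (j in 1:n2) {
    hit <- FALSE
    for (t in seq_len(nrow(offs))) {
      ii <- i + offs$di[t]; jj <- j + offs$dj[t]
      if (ii >= 1 && ii <= n1 && jj >= 1 && jj <= n2 && mask[ii, jj]) { hit <- TRUE; break }
    }
    out[i, j] <- hit
  }
  out
}

oracle_opening <- function(mask, r) oracle_dilate(oracle_erode(mask, r), r)

oracle_closing <- function(mask, r) {
  if (r == 0) return(mask)
  n1 <- nrow(mask); n2 <- ncol(mask)
  pad <- matrix(FALSE, n1 + 2 * r, n2 + 2 * r)
  pad[(r + 1):(r + n1), (r + 1):(r + n2)] <- mask
  res <- oracle_erode(oracle_dilate(pad, r), r)
  res[(r + 1):(r + n1), (r + 1):(r + n2)]
}

oracle_refine_slice <- function(mask, min_size, open_r, close_r) {
  oracle_closing(oracle_opening(oracle_remove_small(mask, min_size), open_r), close_r)
}

# ---- HD95 oracle: exhaustive boundary extraction + all-pairs distances ----
oracle_boundary <- function(mask) {
  dm <- dim(mask)
  pts <- NULL
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    edge <- FALSE
    for (d in 1:3) for (s in c(-1, 1)) {
      q <- p; q[d] <- q[d] + s
      if (q[d] < 1 || q[d] > dm[d] || !mask[q[1], q[2], q[3]]) edge <- TRUE
    }
    if (edge) pts <- rbind(pts, p)
  }
  pts
}

oracle_hd95 <- function(pred, gt, spacing = c(1, 1, 1)) {
  bp <- oracle_boundary(pred)
  bg <- oracle_boundary(gt)
  dmat <- matrix(0, nrow(bp), nrow(bg))
  for (i in seq_len(nrow(bp))) for (j in seq_len(nrow(bg)))
    dmat[i, j] <- sqrt(sum(((bp[i, ] - bg[j, ]) * spacing)^2))
  d1 <- apply(dmat, 1, min)
  d2 <- apply(dmat, 2, min)
  max(oracle_quantile(d1, 0.95), oracle_quantile(d2, 0.95))
}

# ---- synthetic mixtures for clustering tests ----
make_blobs <- function(seed, n_per = 20, d = 4, sd = 0.05, min_sep = 2) {
  set.seed(seed)
  repeat {
    centers <- matrix(rnorm(3 * d, sd = 1.5), 3, d)
    dd <- as.matrix(dist(centers))
    # well-posed fixture: centers separated, and every dimension carries
    # between-center spread so z-scoring cannot amplify within-blob noise
    if (min(dd[upper.tri(dd)]) >= min_sep &&
        min(apply(centers, 2, function(x) diff(range(x)))) >= 1) break
  }
  X <- do.call(rbind, lapply(1:3, function(b)
    matrix(rnorm(n_per * d, 0, sd), n_per, d) +
      matrix(centers[b, ], n_per, d, byrow = TRUE)))
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  list(X = X, labels = rep(1:3, each = n_per))
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  e <- s(rowSums(tab)) * s(colSums(tab)) / choose(length(a), 2)
  (s(tab) - e) / ((s(rowSums(tab)) + s(colSums(tab))) / 2 - e)
}

# minimal patch_set for direct hierarchy tests: each element of
# patch_indices becomes one patch over the given feature rows
construct_patch_set <- function(features, patch_indices) {
  n <- nrow(features)
  cover <- integer(n)
  patches <- lapply(seq_along(patch_indices), function(j) {
    idx <- patch_indices[[j]]
    cover[idx] <<- cover[idx] + 1L
    list(patch_id = j, origin = c(1, 1, 1), index = idx,
         coords = cbind(idx, 1L, 1L),
         features = features[idx, , drop = FALSE])
  })
  structure(list(patches = patches, features = features,
                 coords = cbind(seq_len(n), 1L, 1L),
                 voxel_index = seq_len(n), modalities = colnames(features),
                 raw_features = features, n_covering = cover,
                 dim = c(n, 1L, 1L)),
            class = "patch_set")
}

random_mask_3d <- function(seed, dm = c(7, 7, 7), p = 0.35) {
  set.seed(seed)
  array(runif(prod(dm)) < p, dm)
}

small_phantom_spec <- function(seed = 1, ...) {
  phantom_spec(shape = c(48, 48, 48), brain_half_axes = c(20, 19, 18),
               tumor_half_axes = c(6, 5, 4.5), edema_margin = 3,
               seed = seed, ...)
}
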