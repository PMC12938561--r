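#' Phantom specification
#'
#' Deterministic multi-modal tumor phantom: a brain-shaped ellipsoidal
#' background containing a concentric tumor — necrotic core inside an
#' enhancing rim inside an edema shell. Per-class per-modality mean
#' intensities follow the standard radiological signatures: enhancement is
#' brightest in T1ce, edema in FLAIR/T2, necrosis darkest in T1ce and
#' FLAIR. The FLAIR parenchyma mean defaults to the noise floor (0),
#' emulating a strongly suppressed non-lesional background; see the methods
#' vignette for the rationale and its limits.
#'
#' @param shape grid size (default `c(64, 64, 64)`), 1 mm isotropic.
#' @param spacing voxel spacing in mm.
#' @param brain_center,brain_half_axes brain ellipsoid geometry (voxels).
#' @param tumor_center center of the tumor (voxels).
#' @param tumor_half_axes half-axes of the tumor core region (necrosis +
#'   enhancing rim), in voxels.
#' @param necrotic_fraction necrotic core half-axes as a fraction of
#'   `tumor_half_axes`.
#' @param edema_margin outward margin (voxels) added to `tumor_half_axes`
#'   to form the edema shell's outer ellipsoid.
#' @param class_means per-class per-modality mean intensities: a named list
#'   `brain`, `edema`, `enhancing`, `necrosis`, each a named numeric vector
#'   over `T1`, `T1ce`, `T2`, `FLAIR`.
#' @param modalities modalities to generate (subset containing FLAIR).
#' @param noise_sd Gaussian noise standard deviation (default 0.02 on the
#'   raw intensity scale, which is approximately `[0, 1]`).
#' @param seed RNG seed for the noise.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         spacing = c(1, 1, 1),
                         brain_center = (shape + 1) / 2,
                         brain_half_axes = c(27, 25, 23),
                         tumor_center = brain_center + c(4, 2, 1),
                         tumor_half_axes = c(7, 6, 5),
                         necrotic_fraction = 0.45,
                         edema_margin = 4,
                         class_means = list(
                           brain     = c(T1 = 0.45, T1ce = 0.40, T2 = 0.40, FLAIR = 0.00),
                           edema     = c(T1 = 0.35, T1ce = 0.30, T2 = 0.70, FLAIR = 0.80),
                           enhancing = c(T1 = 0.45, T1ce = 0.85, T2 = 0.55, FLAIR = 0.60),
                           necrosis  = c(T1 = 0.25, T1ce = 0.10, T2 = 0.45, FLAIR = 0.30)),
                         modalities = c("T1", "T1ce", "T2", "FLAIR"),
                         noise_sd = 0.02,
                         seed = 1) {
  stopifnot("FLAIR" %in% modalities, noise_sd >= 0,
            necrotic_fraction > 0, necrotic_fraction < 1, edema_margin >= 0)
  # label assignment must be well-posed: enhancement brightest in T1ce,
  # edema brightest in FLAIR/T2 among the rest, necrosis darkest
  cm <- class_means
  ed_rank <- function(v) if ("T2" %in% modalities) (v[["FLAIR"]] + v[["T2"]]) / 2 else v[["FLAIR"]]
  if (!(cm$enhancing[["T1ce"]] > max(cm$edema[["T1ce"]], cm$necrosis[["T1ce"]])))
    stop("class means violate the T1ce enhancement ordering")
  if (!(ed_rank(cm$edema) > ed_rank(cm$necrosis)))
    stop("class means violate the FLAIR/T2 edema ordering")
  structure(list(shape = as.integer(shape), spacing = spacing,
                 brain_center = brain_center, brain_half_axes = brain_half_axes,
                 tumor_center = tumor_center, tumor_half_axes = tumor_half_axes,
                 necrotic_fraction = necrotic_fraction,
                 edema_margin = edema_margin, class_means = class_means,
                 modalities = modalities, noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

inside_ellipsoid <- function(shape, center, half_axes) {
  x <- ((seq_len(shape[1]) - center[1]) / half_axes[1])^2
  y <- ((seq_len(shape[2]) - center[2]) / half_axes[2])^2
  z <- ((seq_len(shape[3]) - center[3]) / half_axes[3])^2
  outer(outer(x, y, `+`), z, `+`) <= 1
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic multi-modal tumor phantom with ground truth
#'
#' Builds the concentric geometry of [phantom_spec()], assigns each voxel
#' its class mean plus seeded Gaussian noise, clips negative intensities to
#' zero and zeroes everything outside the brain (skull-stripped
#' convention). Bit-identical for a fixed spec.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [multimodal_volume()]) and `labels`
#'   (ground-truth [label_volume()], internal codes).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  sh <- spec$shape
  brain <- inside_ellipsoid(sh, spec$brain_center, spec$brain_half_axes)
  wt <- inside_ellipsoid(sh, spec$tumor_center,
                         spec$tumor_half_axes + spec$edema_margin)
  tc <- inside_ellipsoid(sh, spec$tumor_center, spec$tumor_half_axes)
  nec <- inside_ellipsoid(sh, spec$tumor_center,
                          spec$tumor_half_axes * spec$necrotic_fraction)
  if (any(wt & !brain)) stop("tumor outside brain")
  lab <- array(0L, sh)
  lab[wt] <- 2L   # edema shell
  lab[tc] <- 3L   # enhancing rim
  lab[nec] <- 1L  # necrotic core
  class_of <- lab + 1L  # 1 = brain, 2 = necrosis, 3 = edema, 4 = enhancing
  key <- c("brain", "necrosis", "edema", "enhancing")
  data <- with_seed(spec$seed, {
    out <- list()
    for (m in spec$modalities) {
      means <- vapply(spec$class_means[key], `[[`, 0, m)
      arr <- array(means[class_of], sh)
      arr <- arr + stats::rnorm(length(arr), 0, spec$noise_sd)
      arr[arr < 0] <- 0
      arr[!brain] <- 0
      out[[m]] <- arr
    }
    out
  })
  list(volume = multimodal_volume(data, spacing = spec$spacing),
       labels = label_volume(lab, spacing = spec$spacing))
}

trilinear_upsample <- function(g, shape) {
  # map a coarse grid g onto `shape` by trilinear interpolation
  dg <- dim(g)
  stopifnot(all(dg >= 2))
  ax <- lapply(1:3, function(d) {
    if (dg[d] == 1) rep(1, shape[d])
    else seq(1, dg[d], length.out = shape[d])
  })
  lo <- lapply(seq_along(ax), function(d) pmax(1, pmin(floor(ax[[d]]), dg[d] - 1)))
  fr <- lapply(seq_along(ax), function(d) ax[[d]] - lo[[d]])
  out <- array(0, shape)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wx <- if (cx == 1) fr[[1]] else 1 - fr[[1]]
    wy <- if (cy == 1) fr[[2]] else 1 - fr[[2]]
    wz <- if (cz == 1) fr[[3]] else 1 - fr[[3]]
    w <- outer(outer(wx, wy), wz)
    out <- out + w * g[lo[[1]] + cx, lo[[2]] + cy, lo[[3]] + cz]
  }
  out
}

box_blur_slice <- function(m) {
  # 3x3 box blur with edge replication
  p <- m[c(1, 1:nrow(m), nrow(m)), c(1, 1:ncol(m), ncol(m))]
  acc <- matrix(0, nrow(m), ncol(m))
  for (dx in 0:2) for (dy in 0:2)
    acc <- acc + p[dx + 1:nrow(m), dy + 1:ncol(m)]
  acc / 9
}

#' Apply an image-quality perturbation to a volume
#'
#' Operators mirroring common acquisition degradations:
#' * `gaussian_noise` — seeded i.i.d. noise of standard deviation `sigma`
#'   added inside the brain support (negative results clipped to 0);
#' * `bias_field` — multiplication by one shared smooth low-frequency field
#'   with peak deviation `amplitude` (e.g. 0.2 for a 20% bias);
#' * `downsample` — block-average by `factor` then re-expansion to the
#'   original grid (resolution loss, e.g. 1 mm to 2 mm);
#' * `motion` — a seeded random fraction of axial slices replaced by
#'   shifted, blurred copies of themselves.
#'
#' @param volume a [multimodal_volume()].
#' @param kind one of `"gaussian_noise"`, `"bias_field"`, `"downsample"`,
#'   `"motion"`.
#' @param sigma noise standard deviation (gaussian_noise).
#' @param amplitude peak multiplicative deviation (bias_field).
#' @param factor integer downsampling factor dividing every grid dimension.
#' @param slice_fraction fraction of axial slices affected (motion).
#' @param shift in-plane shift in voxels for motion-corrupted slices.
#' @param seed RNG seed for the stochastic operators.
#' @return a perturbed [multimodal_volume()].
#' @export
perturb <- function(volume, kind = c("gaussian_noise", "bias_field",
                                     "downsample", "motion"),
                    sigma = 0.05, amplitude = 0.2, factor = 2,
                    slice_fraction = 0.125, shift = 2, seed = 1) {
  kind <- match.arg(kind)
  sh <- volume$dim
  support <- Reduce(`|`, lapply(volume$data, function(a) a > 0))
  data <- switch(kind,
    gaussian_noise = with_seed(seed, lapply(volume$data, function(a) {
      if (sigma == 0) return(a)
      out <- a
      out[support] <- out[support] + stats::rnorm(sum(support), 0, sigma)
      out[out < 0] <- 0
      out
    })),
    bias_field = {
      g <- with_seed(seed, array(stats::rnorm(4 * 4 * 4), c(4, 4, 4)))
      g <- trilinear_upsample(g, sh)
      g <- g / max(abs(g))
      field <- 1 + amplitude * g
      lapply(volume$data, function(a) a * field)
    },
    downsample = {
      if (any(sh %% factor != 0)) stop("grid not divisible by factor")
      lapply(volume$data, function(a) {
        cs <- sh %/% factor
        blk <- array(a, c(factor, cs[1], factor, cs[2], factor, cs[3]))
        small <- apply(blk, c(2, 4, 6), mean)
        big <- small[rep(seq_len(cs[1]), each = factor),
                     rep(seq_len(cs[2]), each = factor),
                     rep(seq_len(cs[3]), each = factor)]
        array(big, sh)
      })
    },
    motion = {
      nz <- sh[3]
      n_bad <- max(1L, round(slice_fraction * nz))
      bad <- with_seed(seed, sort(sample.int(nz, n_bad)))
      lapply(volume$data, function(a) {
        for (z in bad) {
          sl <- a[, , z]
          shifted <- shift_pad(sl, c(shift, 0), fill = 0)
          a[, , z] <- box_blur_slice(shifted)
        }
        a
      })
    })
  multimodal_volume(data, spacing = volume$spacing)
}
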