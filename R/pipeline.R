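#' Full pipeline configuration
#'
#' Groups every tunable of the two-stage pipeline, with defaults equal to
#' the full-method configuration: percentile normalization (2/98), Sauvola
#' thresholding (15x15 window, k = 0.5), per-slice morphology (S_min = 64,
#' opening radius 2, closing radius 3), strict AND fusion, patch-wise
#' affinity propagation (5^3 patches, 50% overlap, median preference,
#' 200/15 iteration control) with hierarchical refinement (max 3 levels).
#' The ablation switches select the degraded arms used by [run_ablation()].
#'
#' @param normalization `"percentile"` or `"minmax"` (ablation arm).
#' @param low_percentile,high_percentile percentile bounds.
#' @param threshold `"sauvola"` or `"otsu"` (ablation arm).
#' @param sauvola a [sauvola_params()].
#' @param morphology logical: per-slice morphological refinement on/off.
#' @param morph a [morphology_params()].
#' @param fusion fusion strategy (`"AND"`, `"MAJORITY"`, `"OR"`,
#'   `"SINGLE_AXIAL"`).
#' @param clustering `"ap"` (affinity propagation) or `"kmeans"`
#'   (fixed k = 3 Lloyd's algorithm ablation arm).
#' @param hierarchy logical: hierarchical exemplar refinement on/off.
#' @param ap an [ap_config()].
#' @param kmeans_k,kmeans_restarts k-means ablation arm settings.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(normalization = c("percentile", "minmax"),
                            low_percentile = 2, high_percentile = 98,
                            threshold = c("sauvola", "otsu"),
                            sauvola = sauvola_params(),
                            morphology = TRUE,
                            morph = morphology_params(),
                            fusion = c("AND", "MAJORITY", "OR", "SINGLE_AXIAL"),
                            clustering = c("ap", "kmeans"),
                            hierarchy = TRUE,
                            ap = ap_config(),
                            kmeans_k = 3, kmeans_restarts = 10) {
  structure(list(normalization = match.arg(normalization),
                 low_percentile = low_percentile,
                 high_percentile = high_percentile,
                 threshold = match.arg(threshold),
                 sauvola = sauvola, morphology = isTRUE(morphology),
                 morph = morph, fusion = match.arg(fusion),
                 clustering = match.arg(clustering),
                 hierarchy = isTRUE(hierarchy), ap = ap,
                 kmeans_k = kmeans_k, kmeans_restarts = kmeans_restarts),
            class = "pipeline_config")
}

kmeans_partition <- function(features, k, restarts, seed) {
  km <- with_seed(seed, stats::kmeans(features, centers = k, nstart = restarts))
  # nearest member to each centroid stands in as the cluster's exemplar
  exemplars <- vapply(seq_len(k), function(j) {
    rows <- which(km$cluster == j)
    d <- rowSums(abs(features[rows, , drop = FALSE] -
                       matrix(km$centers[j, ], length(rows), ncol(features), byrow = TRUE)))
    rows[which.min(d)]
  }, 1L)
  list(assignment = as.integer(km$cluster), exemplars = exemplars,
       n_clusters = k, level = 1L)
}

#' Stage 2: subregion labeling inside the whole-tumor mask
#'
#' Extracts overlapping multi-modal patches, clusters each by modified
#' affinity propagation, refines hierarchically, selects the best partition
#' by the intra/inter validity score, and maps clusters to necrosis /
#' edema / enhancing tumor by radiological-prior ranking. Nonzero labels
#' appear exactly on the mask.
#'
#' @param volume a [multimodal_volume()] with raw intensities.
#' @param mask 3D logical whole-tumor mask from [run_stage1()].
#' @param config a [pipeline_config()].
#' @param seed RNG seed; only the k-means ablation arm consumes it (the
#'   affinity-propagation path is fully deterministic).
#' @return a [label_volume()] with attributes `partition`, `profiles`,
#'   `label_map`.
#' @export
run_stage2 <- function(volume, mask, config = pipeline_config(), seed = 1) {
  if (!any(mask)) stop("empty mask")
  norm <- normalize_volume(volume, method = config$normalization,
                           low_percentile = config$low_percentile,
                           high_percentile = config$high_percentile)
  ps <- extract_patches(norm, mask, config$ap)
  if (config$clustering == "kmeans") {
    part <- kmeans_partition(ps$features, config$kmeans_k,
                             config$kmeans_restarts, seed)
  } else {
    level1 <- lapply(ps$patches, function(p)
      run_affinity_propagation(p$features, config$ap, sigma = rep(1, ncol(p$features))))
    cfg <- config$ap
    if (!config$hierarchy) cfg$max_hierarchy_levels <- 1L
    hr <- hierarchical_refine(level1, ps, cfg)
    part <- select_optimal_partition(hr$candidates, ps$features)
  }
  profiles <- cluster_profiles(part, ps$raw_features)
  labmap <- assign_labels(profiles)
  arr <- array(0L, volume$dim)
  arr[ps$voxel_index] <- labmap[part$assignment]
  structure(label_volume(arr, spacing = volume$spacing),
            partition = part, profiles = profiles, label_map = labmap)
}

#' Run the full two-stage segmentation
#'
#' @param volume a [multimodal_volume()] (raw intensities, FLAIR required).
#' @param config a [pipeline_config()].
#' @param seed passed to [run_stage2()] (k-means arm only).
#' @return a [label_volume()]; all-background (with a warning) when stage 1
#'   finds no tumor.
#' @export
segment_tumor <- function(volume, config = pipeline_config(), seed = 1) {
  mask <- run_stage1(volume, config)
  if (!any(mask)) {
    warning("stage 1 produced an empty mask; returning background-only labels")
    return(label_volume(array(0L, volume$dim), spacing = volume$spacing))
  }
  out <- run_stage2(volume, mask, config, seed = seed)
  attr(out, "stage1_mask") <- mask
  out
}

apply_variant <- function(config, variant) {
  switch(variant,
    baseline = config,
    minmax_normalization = { config$normalization <- "minmax"; config },
    otsu_threshold = { config$threshold <- "otsu"; config },
    no_morphology = { config$morphology <- FALSE; config },
    kmeans_clustering = { config$clustering <- "kmeans"; config },
    no_hierarchy = { config$hierarchy <- FALSE; config },
    fusion_and = { config$fusion <- "AND"; config },
    fusion_majority = { config$fusion <- "MAJORITY"; config },
    fusion_or = { config$fusion <- "OR"; config },
    fusion_single_axial = { config$fusion <- "SINGLE_AXIAL"; config },
    stop("unknown variant key: ", variant))
}

#' Component ablation harness
#'
#' Runs each requested pipeline variant on the same phantom cases (shared
#' seed set) and tabulates the per-region scores.
#'
#' @param config baseline [pipeline_config()].
#' @param variants character vector of variant keys (`baseline`, `minmax_normalization`,
#'   `otsu_threshold`, `no_morphology`, `kmeans_clustering`,
#'   `no_hierarchy`, `fusion_*`).
#' @param seeds phantom seeds shared across variants.
#' @param spec base [phantom_spec()]; its `seed` field is replaced per case.
#' @return data.frame with `variant`, `seed`, and the [evaluate_case()]
#'   columns.
#' @export
run_ablation <- function(config = pipeline_config(),
                         variants = c("baseline", "minmax_normalization",
                                      "otsu_threshold", "no_morphology",
                                      "kmeans_clustering", "no_hierarchy"),
                         seeds = 0:4, spec = phantom_spec()) {
  cases <- lapply(seeds, function(s) {
    spec$seed <- s
    generate_phantom(spec)
  })
  rows <- list()
  for (v in variants) {
    cfg <- apply_variant(config, v)
    for (i in seq_along(seeds)) {
      pred <- segment_tumor(cases[[i]]$volume, cfg, seed = seeds[i])
      sc <- evaluate_case(pred, cases[[i]]$labels, spec$spacing)
      sc$variant <- v; sc$seed <- seeds[i]
      rows[[length(rows) + 1L]] <- sc
    }
  }
  out <- do.call(rbind, rows)
  out[, c("variant", "seed", setdiff(names(out), c("variant", "seed")))]
}

#' Stage-1 fusion-strategy comparison
#'
#' Evaluates the binary whole-tumor mask of each fusion strategy directly
#' against the phantom's ground-truth whole tumor.
#'
#' @param config baseline [pipeline_config()].
#' @param strategies fusion strategies to compare.
#' @param seeds phantom seeds.
#' @param spec base [phantom_spec()].
#' @return data.frame with `strategy`, `seed`, `dice`, `hd95`, `recall`,
#'   `precision`, `fp`.
#' @export
run_fusion_ablation <- function(config = pipeline_config(),
                                strategies = c("AND", "MAJORITY", "OR",
                                               "SINGLE_AXIAL"),
                                seeds = 0:4, spec = phantom_spec()) {
  rows <- list()
  for (s in seeds) {
    spec$seed <- s
    case <- generate_phantom(spec)
    gt_wt <- compose_regions(case$labels)$WT
    for (st in strategies) {
      cfg <- config; cfg$fusion <- st
      mask <- run_stage1(case$volume, cfg)
      cc <- recall_precision(mask, gt_wt)
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = st, seed = s,
        dice = dice(mask, gt_wt),
        hd95 = hd95(mask, gt_wt, spec$spacing),
        recall = cc$recall, precision = cc$precision, fp = cc$fp)
    }
  }
  do.call(rbind, rows)
}

#' Robustness harness over image-quality perturbations
#'
#' Applies each perturbation to fresh phantoms (shared seeds), runs the
#' full pipeline, and tabulates scores next to the clean baseline.
#'
#' @param config a [pipeline_config()].
#' @param perturbations named list; each element is a list with `kind` and
#'   any [perturb()] arguments, e.g.
#'   `list(noise_05 = list(kind = "gaussian_noise", sigma = 0.05))`.
#'   A `clean` row is always included.
#' @param seeds phantom seeds.
#' @param spec base [phantom_spec()].
#' @return data.frame with `perturbation`, `seed` and score columns;
#'   `delta_dice` is the per-seed WT Dice change versus clean.
#' @export
run_robustness <- function(config = pipeline_config(),
                           perturbations = list(
                             noise_05 = list(kind = "gaussian_noise", sigma = 0.05),
                             noise_10 = list(kind = "gaussian_noise", sigma = 0.10),
                             bias_20 = list(kind = "bias_field", amplitude = 0.2),
                             downsample_2x = list(kind = "downsample", factor = 2),
                             motion = list(kind = "motion", slice_fraction = 0.125)),
                           seeds = 0:4, spec = phantom_spec()) {
  rows <- list()
  for (s in seeds) {
    spec$seed <- s
    case <- generate_phantom(spec)
    runs <- c(list(clean = NULL), perturbations)
    clean_wt <- NA_real_
    for (nm in names(runs)) {
      vol <- if (is.null(runs[[nm]])) case$volume else
        do.call(perturb, c(list(volume = case$volume, seed = s + 1000L), runs[[nm]]))
      pred <- segment_tumor(vol, config, seed = s)
      sc <- evaluate_case(pred, case$labels, spec$spacing)
      if (nm == "clean") clean_wt <- sc$dice[sc$region == "WT"]
      sc$perturbation <- nm; sc$seed <- s
      sc$delta_dice <- ifelse(sc$region == "WT",
                              sc$dice[sc$region == "WT"] - clean_wt, NA_real_)
      rows[[length(rows) + 1L]] <- sc
    }
  }
  out <- do.call(rbind, rows)
  out[, c("perturbation", "seed", setdiff(names(out), c("perturbation", "seed")))]
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, seeds and package version needed to
#' reproduce a run bit-for-bit.
#'
#' @param path output JSON file.
#' @param config a [pipeline_config()].
#' @param seeds seed set used.
#' @param extra optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, seeds, extra = list()) {
  payload <- c(list(
    package = "glioseg",
    version = as.character(utils::packageVersion("glioseg")),
    r_version = R.version.string,
    seeds = seeds,
    config = unclass(rapply(config, unclass, how = "replace"))), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
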