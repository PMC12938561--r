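test_that("constant slice collapses the Sauvola threshold to m(1 - k)", {
  sl <- matrix(0.8, 9, 9)
  tm <- sauvola_threshold_map(sl, sauvola_params(window = 5, k = 0.5, R = 0.5))
  expect_equal(tm, matrix(0.8 * 0.5, 9, 9))
})

test_that("k = 0 reduces the threshold map to the local mean", {
  set.seed(11)
  sl <- matrix(runif(81), 9, 9)
  tm <- sauvola_threshold_map(sl, sauvola_params(window = 3, k = 0, R = 0.5))
  or <- oracle_sauvola(sl, 3, 0, 0.5)
  expect_equal(tm, or, tolerance = 1e-12)
})

test_that("threshold map equals the brute-force windowed-statistics oracle", {
  # pinned checkerboard case
  cb <- matrix(rep(c(0, 1), length.out = 25), 5, 5)
  tm <- sauvola_threshold_map(cb, sauvola_params(window = 3, k = 0.5, R = 0.5))
  expect_lt(max(abs(tm - oracle_sauvola(cb, 3, 0.5, 0.5))), 1e-10)
  # random slices, several window sizes
  set.seed(123)
  for (w in c(3, 5, 7)) {
    sl <- matrix(runif(15 * 12), 15, 12)
    tm <- sauvola_threshold_map(sl, sauvola_params(window = w, k = 0.5, R = 0.5))
    expect_lt(max(abs(tm - oracle_sauvola(sl, w, 0.5, 0.5))), 1e-10)
  }
})

test_that("binarization is strict and shape-checked", {
  expect_identical(binarize(matrix(0.5), matrix(0.5)), matrix(FALSE))
  expect_identical(binarize(matrix(0.6), matrix(0.5)), matrix(TRUE))
  z <- matrix(0, 4, 4)
  expect_true(!any(binarize(z, matrix(0.1, 4, 4))))
  expect_error(binarize(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(sauvola_threshold_map(array(0, c(2, 2, 2))), "non-2D")
})

test_that("small components are removed by the strict retention rule", {
  m <- matrix(FALSE, 10, 10)
  m[1:3, 1] <- TRUE                    # size 3
  m[6:10, 5:6] <- TRUE                 # size 10
  out <- remove_small_components(m, min_size = 5)
  expect_equal(sum(out), 10)
  expect_true(all(out[6:10, 5:6]))
  # strictness: a component of exactly min_size is dropped
  expect_equal(sum(remove_small_components(m, min_size = 10)), 0)
})

test_that("closing fills interior holes", {
  m <- matrix(FALSE, 11, 11)
  m[3:9, 3:9] <- TRUE
  m[6, 6] <- FALSE
  out <- refine_slice(m, morphology_params(min_component_size = 5,
                                           opening_radius = 0,
                                           closing_radius = 1))
  expect_true(out[6, 6])
})

test_that("per-slice refinement matches the morphology oracle on random masks", {
  for (seed in 1:12) {
    set.seed(seed)
    m <- matrix(runif(32 * 32) < 0.45, 32, 32)
    got <- refine_slice(m, morphology_params(8, 2, 3))
    want <- oracle_refine_slice(m, 8, 2, 3)
    expect_identical(got, want)
  }
})

test_that("removal never adds voxels and closing is extensive", {
  for (seed in 1:10) {
    set.seed(seed)
    m <- matrix(runif(24 * 24) < 0.4, 24, 24)
    rem <- remove_small_components(m, 6)
    expect_true(all(!rem | m))
    op <- binary_opening(rem, 2)
    cl <- binary_closing(op, 3)
    expect_true(all(!op | cl))  # closing keeps its own input
  }
  expect_identical(refine_slice(matrix(FALSE, 8, 8)), matrix(FALSE, 8, 8))
})

test_that("per-plane thresholding stacks slices and handles empty volumes", {
  z <- array(0, c(12, 12, 12))
  for (p in c("axial", "coronal", "sagittal")) {
    m <- threshold_plane(z, p, sauvola_params(window = 5),
                         morphology_params(0, 0, 0))
    expect_identical(dim(m), dim(z))
    expect_false(any(m))
  }
  expect_error(threshold_plane(z, "oblique"), "arg")
})

test_that("fusion follows the per-voxel truth table", {
  combos <- expand.grid(a = c(FALSE, TRUE), c = c(FALSE, TRUE), s = c(FALSE, TRUE))
  masks <- list(axial = array(combos$a, c(8, 1, 1)),
                coronal = array(combos$c, c(8, 1, 1)),
                sagittal = array(combos$s, c(8, 1, 1)))
  votes <- combos$a + combos$c + combos$s
  expect_equal(as.vector(fuse_masks(masks, "AND")), votes == 3)
  expect_equal(as.vector(fuse_masks(masks, "MAJORITY")), votes >= 2)
  expect_equal(as.vector(fuse_masks(masks, "OR")), votes >= 1)
  expect_equal(as.vector(fuse_masks(masks, "SINGLE_AXIAL")), combos$a)
})

test_that("fusion nests monotonically in the vote threshold", {
  for (seed in 1:8) {
    set.seed(seed)
    masks <- list(axial = array(runif(6^3) < 0.5, c(6, 6, 6)),
                  coronal = array(runif(6^3) < 0.5, c(6, 6, 6)),
                  sagittal = array(runif(6^3) < 0.5, c(6, 6, 6)))
    a <- fuse_masks(masks, "AND")
    m <- fuse_masks(masks, "MAJORITY")
    o <- fuse_masks(masks, "OR")
    expect_true(all(!a | m))
    expect_true(all(!m | o))
  }
  bad <- list(axial = array(TRUE, c(2, 2, 2)), coronal = array(TRUE, c(2, 2, 2)),
              sagittal = array(TRUE, c(3, 2, 2)))
  expect_error(fuse_masks(bad, "AND"), "shape")
})

test_that("volumetric cleanup is identity when disabled and filters when on", {
  m <- array(FALSE, c(12, 12, 12))
  m[2:3, 2:3, 2:3] <- TRUE            # 8 voxels
  m[6:11, 6:11, 6:11] <- TRUE         # 216 voxels
  expect_identical(postfuse_cleanup(m, morphology_params()), m)
  on <- morphology_params(cleanup_3d = TRUE, min_component_size_3d = 50,
                          closing_radius_3d = 1)
  out <- postfuse_cleanup(m, on)
  expect_false(any(out[2:3, 2:3, 2:3]))
  expect_true(all(out[6:11, 6:11, 6:11]))
  # 1-voxel cavity is filled by the spherical closing
  cav <- array(FALSE, c(9, 9, 9)); cav[2:8, 2:8, 2:8] <- TRUE; cav[5, 5, 5] <- FALSE
  expect_true(postfuse_cleanup(cav, morphology_params(cleanup_3d = TRUE,
                                                      min_component_size_3d = 0,
                                                      closing_radius_3d = 1))[5, 5, 5])
})

test_that("a bright ellipsoid is recovered in every plane", {
  spec <- small_phantom_spec(seed = 3)
  case <- generate_phantom(spec)
  flair <- percentile_normalize(case$volume$data$FLAIR)
  gt <- compose_regions(case$labels)$WT
  for (p in c("axial", "coronal", "sagittal")) {
    m <- threshold_plane(flair, p)
    expect_identical(dim(m), dim(flair))
    expect_gt(sum(m & gt) / sum(gt), 0.8)
  }
})
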