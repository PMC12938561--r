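cube <- function(dm, ix) { m <- array(FALSE, dm); m[ix] <- TRUE; m }

test_that("Dice handles the canonical cases", {
  dm <- c(4, 4, 4)
  a <- cube(dm, 1:6)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(cube(dm, 1:4), cube(dm, 3:8)), 2 * 2 / 10)  # |P|=4,|G|=6,|I|=2
  p <- cube(dm, 1:4); g <- cube(dm, c(1:3, 5:7))                 # tp=3 of 4 vs 6
  expect_equal(dice(p, g), 2 * 3 / 10)
  expect_equal(dice(cube(dm, 1:3), cube(dm, 10:12)), 0)
  expect_equal(dice(array(FALSE, dm), array(FALSE, dm)), 1)      # both empty
  expect_error(dice(a, array(FALSE, c(3, 3, 3))), "shape")
})

test_that("HD95 matches single-pair geometry and empty-mask convention", {
  dm <- c(9, 9, 9)
  a <- array(FALSE, dm); a[2, 5, 5] <- TRUE
  b <- array(FALSE, dm); b[5, 5, 5] <- TRUE
  expect_equal(hd95(a, b), 3)                      # 3 voxels apart, 1 mm iso
  expect_equal(hd95(a, b, spacing = c(2, 1, 1)), 6)
  expect_equal(hd95(b, b), 0)
  expect_true(is.na(hd95(array(FALSE, dm), b)))
})

test_that("HD95 equals the all-pairs boundary-distance oracle", {
  for (seed in 1:10) {
    p <- random_mask_3d(seed)
    g <- random_mask_3d(seed + 100)
    if (!any(p) || !any(g)) next
    expect_equal(hd95(p, g), oracle_hd95(p, g), tolerance = 1e-10)
  }
})

test_that("Dice and HD95 are symmetric and HD95 is below the full Hausdorff", {
  for (seed in 11:16) {
    p <- random_mask_3d(seed); g <- random_mask_3d(seed + 50)
    if (!any(p) || !any(g)) next
    expect_equal(dice(p, g), dice(g, p))
    expect_equal(hd95(p, g), hd95(g, p))
    expect_lte(hd95(p, g), hd95(p, g, percentile = 1) + 1e-12)
  }
})

test_that("recall and precision come from the confusion table", {
  dm <- c(4, 4, 2)
  p <- cube(dm, c(1, 2, 3, 9, 10))      # 5 predicted
  g <- cube(dm, c(1, 2, 3, 4))          # 4 true
  cc <- recall_precision(p, g)
  expect_equal(cc$tp, 3); expect_equal(cc$fp, 2); expect_equal(cc$fn, 1)
  expect_equal(cc$recall, 0.75)
  expect_equal(cc$precision, 0.6)
  same <- recall_precision(g, g)
  expect_equal(same$recall, 1); expect_equal(same$precision, 1)
  e <- recall_precision(array(FALSE, dm), g)
  expect_equal(e$recall, 0)
  expect_true(is.na(e$precision))
  # brute-force confusion oracle on random masks
  for (seed in 21:26) {
    p <- random_mask_3d(seed); g <- random_mask_3d(seed + 7)
    cc <- recall_precision(p, g)
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(p)) {
      if (p[i] && g[i]) tp <- tp + 1
      if (p[i] && !g[i]) fp <- fp + 1
      if (!p[i] && g[i]) fn <- fn + 1
    }
    expect_equal(c(cc$tp, cc$fp, cc$fn), c(tp, fp, fn))
  }
})

test_that("case evaluation scores the three nested regions", {
  dm <- c(8, 8, 8)
  gt <- array(0L, dm)
  gt[2:7, 2:7, 4] <- 2L; gt[3:6, 3:6, 4] <- 3L; gt[4:5, 4:5, 4] <- 1L
  self <- evaluate_case(gt, gt)
  expect_equal(self$dice, c(1, 1, 1))
  expect_equal(self$hd95, c(0, 0, 0))
  # relabeling necrosis as edema leaves WT untouched but degrades TC
  pred <- gt; pred[pred == 1L] <- 2L
  sc <- evaluate_case(pred, gt)
  expect_equal(sc$dice[sc$region == "WT"], 1)
  expect_lt(sc$dice[sc$region == "TC"], 1)
  expect_equal(sc$dice[sc$region == "ET"], 1)
})

test_that("per-region scores agree with a per-region confusion oracle", {
  set.seed(33)
  for (rep in 1:4) {
    dm <- c(6, 6, 6)
    gt <- array(sample(0:3, prod(dm), TRUE, prob = c(.7, .1, .1, .1)), dm)
    pr <- array(sample(0:3, prod(dm), TRUE, prob = c(.7, .1, .1, .1)), dm)
    sc <- evaluate_case(pr, gt)
    regions <- list(WT = 1:3, TC = c(1, 3), ET = 3)
    for (rg in names(regions)) {
      pm <- array(pr %in% regions[[rg]], dm)
      gm <- array(gt %in% regions[[rg]], dm)
      tp <- sum(pm & gm)
      if (sum(pm) + sum(gm) == 0) next
      expect_equal(sc$dice[sc$region == rg], 2 * tp / (sum(pm) + sum(gm)))
    }
  }
})
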