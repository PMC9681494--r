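# Binarization, edge/contour counting, and segmentation metrics.

disk_mask <- function(H, W, ci, cj, r) {
  di <- outer(1:H - ci, rep(1, W)); dj <- outer(rep(1, H), 1:W - cj)
  matrix(as.integer(di^2 + dj^2 <= r^2), H, W)
}

test_that("binarization thresholds at 0.5 and is idempotent on binaries", {
  expect_equal(binarize_map(matrix(0.6, 4, 4)), matrix(1L, 4, 4))
  expect_equal(binarize_map(matrix(0.4, 4, 4)), matrix(0L, 4, 4))
  m <- matrix(c(0L, 1L), 4, 4)
  expect_equal(binarize_map(m * 1.0), m)
  expect_error(binarize_map(matrix(1.5, 2, 2)), "\\[0,1\\]")
})

test_that("an empty mask counts zero lesions", {
  expect_equal(count_lesions(matrix(0L, 32, 32)), 0L)
})

test_that("well-separated disks count exactly", {
  m <- disk_mask(64, 64, 12, 12, 5) + disk_mask(64, 64, 12, 40, 5) +
    disk_mask(64, 64, 45, 25, 5)
  expect_equal(count_lesions(m), 3)
})

test_that("an overlapping-ellipse union counts as one lesion", {
  H <- 64
  m <- matrix(0L, H, H)
  for (off in list(c(0, 0), c(4, 3), c(-3, 5))) {
    di <- outer(1:H - (30 + off[1]), rep(1, H))
    dj <- outer(rep(1, H), 1:H - (30 + off[2]))
    m <- m | ((di / 8)^2 + (dj / 5)^2 <= 1)
  }
  m <- matrix(as.integer(m), H, H)
  expect_equal(cc_oracle(m), 1)
  expect_equal(count_lesions(m), 1)
})

test_that("a lesion with an interior hole counts once (outer contour only)", {
  m <- disk_mask(48, 48, 24, 24, 12) - disk_mask(48, 48, 24, 24, 5)
  expect_equal(count_lesions(m), 1)
})

test_that("components touching the image border are still counted", {
  m <- disk_mask(40, 40, 2, 20, 6) + disk_mask(40, 40, 30, 20, 5)
  expect_equal(count_lesions(m), 2)
})

test_that("contour counting agrees with connected components on generated masks", {
  set.seed(21)
  for (s in 1:10) {
    cnt <- c(MA = sample(0:5, 1), EX = sample(0:3, 1), HEM = sample(0:2, 1))
    g <- generate_fundus_image(tiny_spec(cnt, seed = 400 + s))
    for (cl in lesion_classes())
      expect_equal(count_lesions(g$masks[[cl]]), cc_oracle(g$masks[[cl]]),
                   label = sprintf("seed %d class %s", 400 + s, cl))
  }
})

test_that("the minimum-area filter drops small objects only", {
  m <- disk_mask(64, 64, 15, 15, 8) + disk_mask(64, 64, 45, 45, 2)
  expect_equal(count_lesions(m), 2)
  expect_equal(count_lesions(m, min_area = 30), 1)
})

test_that("non-binary input is rejected", {
  expect_error(count_lesions(matrix(0.5, 8, 8)), "binary")
})

test_that("canny finds a closed edge ring around a synthetic step edge", {
  m <- disk_mask(48, 48, 24, 24, 10)
  ed <- canny_edges(m * 1.0, sigma = 0)
  expect_gt(sum(ed), 0)
  # edges hug the boundary: all edge pixels within 2 px of the disk rim
  dist_in <- abs(sqrt(outer(1:48 - 24, rep(1, 48))^2 +
                        outer(rep(1, 48), 1:48 - 24)^2) - 10)
  expect_true(all(dist_in[ed] <= 2.5))
})

test_that("segmentation metrics reproduce their closed forms", {
  a <- disk_mask(32, 32, 16, 16, 6)
  m <- seg_metrics(a, a)
  expect_equal(m$recall, 1); expect_equal(m$precision, 1)
  expect_equal(m$f1, 1); expect_equal(m$accuracy, 1); expect_equal(m$iou, 1)
  b <- disk_mask(32, 32, 8, 8, 4); d <- disk_mask(32, 32, 24, 24, 4)
  m2 <- seg_metrics(b, d)
  expect_equal(m2$recall, 0); expect_equal(m2$precision, 0)
  expect_equal(m2$iou, 0)
  m3 <- metrics_from_confusion(c(TP = 3, FP = 1, FN = 1, TN = 5))
  expect_equal(m3$precision, 0.75)
  expect_equal(m3$recall, 0.75)
  expect_equal(m3$f1, 0.75)
  expect_equal(m3$accuracy, 0.8)
  expect_equal(m3$iou, 0.6)
})

test_that("zero denominators give explicit undefined markers, never 0", {
  m <- metrics_from_confusion(c(TP = 0, FP = 0, FN = 0, TN = 10))
  expect_true(is.na(m$recall))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$iou))
  expect_equal(m$accuracy, 1)
  expect_error(seg_metrics(matrix(0L, 2, 2), matrix(0L, 3, 3)), "equal")
})

test_that("F1 is the harmonic mean of precision and recall; IoU <= F1", {
  set.seed(22)
  for (i in 1:20) {
    pred <- matrix(as.integer(runif(400) < 0.3), 20, 20)
    truth <- matrix(as.integer(runif(400) < 0.3), 20, 20)
    m <- seg_metrics(pred, truth)
    if (!is.na(m$f1)) {
      expect_equal(m$f1, 2 * m$precision * m$recall /
                     (m$precision + m$recall))
      expect_lte(m$iou, m$f1 + 1e-12)
    }
  }
})
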