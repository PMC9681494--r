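# Tiling, augmentation, and probability-map reconstruction.

test_that("anchor placement covers the image with a final snap-back anchor", {
  expect_equal(tile_anchors(512, 256, 128), c(0, 128, 256))
  expect_equal(tile_anchors(256, 256, 128), 0)
  expect_equal(tile_anchors(300, 256, 128), c(0, 44))
  expect_error(tile_anchors(100, 256, 128), "exceeds")
  expect_error(tile_anchors(100, 50, 0), "stride")
  expect_error(tile_anchors(100, 50, 51), "stride")
})

test_that("patch counts follow the anchor grid", {
  m <- matrix(runif(512 * 512), 512, 512)
  expect_length(tile_patches(m, 256, 128)$patches, 9)
  expect_length(tile_patches(matrix(0, 256, 256), 256, 128)$patches, 1)
  ps <- tile_patches(matrix(0, 300, 300), 256, 128)
  expect_length(ps$patches, 4)
  expect_equal(ps$placements[1, ], c(row = 0, col = 0))
})

test_that("tile then reconstruct is the identity for any stride", {
  set.seed(10)
  M <- matrix(runif(200 * 180), 200, 180)
  for (stride in c(37, 64, 100, 128)) {
    ps <- tile_patches(M, 128, stride)
    R <- reconstruct_map(ps$patches, ps$placements, 200, 180)
    expect_equal(R, M, label = sprintf("stride %d", stride))
  }
})

test_that("overlap merging averages disagreeing predictions", {
  p0 <- matrix(0, 4, 4); p1 <- matrix(1, 4, 4)
  # two patches overlap in columns 3:4
  out <- reconstruct_map(list(p0, p1), rbind(c(0, 0), c(0, 2)), 4, 6)
  expect_equal(out[, 3:4], matrix(0.5, 4, 2))
  expect_equal(out[, 1:2], matrix(0, 4, 2))
  expect_equal(out[, 5:6], matrix(1, 4, 2))
  mx <- reconstruct_map(list(p0, p1), rbind(c(0, 0), c(0, 2)), 4, 6,
                        merge = "max")
  expect_equal(mx[, 3:4], matrix(1, 4, 2))
  # constant-1 patches reconstruct to a constant-1 map
  ones <- reconstruct_map(list(p1, p1), rbind(c(0, 0), c(0, 2)), 4, 6)
  expect_equal(ones, matrix(1, 4, 6))
})

test_that("reconstruction stays within the range of patch predictions", {
  set.seed(11)
  maps <- lapply(1:4, function(i) matrix(runif(64, 0.2, 0.8), 8, 8))
  out <- reconstruct_map(maps, rbind(c(0, 0), c(0, 4), c(4, 0), c(4, 4)),
                         12, 12)
  expect_gte(min(out), 0.2)
  expect_lte(max(out), 0.8)
})

test_that("uncovered pixels are rejected", {
  expect_error(reconstruct_map(list(matrix(0, 4, 4)), rbind(c(0, 0)), 8, 8),
               "cover")
})

test_that("flips are involutions and conserve mask area with 90-degree turns", {
  set.seed(12)
  img <- matrix(runif(64 * 64), 64, 64)
  msk <- matrix(as.integer(runif(64 * 64) < 0.2), 64, 64)
  t1 <- transform_patch_pair(img, msk, hflip = TRUE)
  t2 <- transform_patch_pair(t1$img, t1$mask, hflip = TRUE)
  expect_equal(t2$img, img)
  expect_equal(t2$mask, msk)
  for (ang in c(0, 90, 180, 270)) {
    tr <- transform_patch_pair(img, msk, angle = ang)
    expect_equal(sum(tr$mask), sum(msk), label = sprintf("angle %d", ang))
  }
  tr <- transform_patch_pair(img, msk, hflip = TRUE, vflip = TRUE)
  expect_equal(sum(tr$mask), sum(msk))
})

test_that("identical transforms keep image and mask geometrically aligned", {
  n <- 32
  di <- outer(1:n - 10, rep(1, n)); dj <- outer(rep(1, n), 1:n - 22)
  disk <- (di^2 + dj^2) <= 25
  img <- ifelse(disk, 1, 0) * 1.0
  msk <- matrix(as.integer(disk), n, n)
  for (ang in c(37, 90, 201)) {
    tr <- transform_patch_pair(img, msk, angle = ang)
    agree <- mean((tr$img >= 0.5) == (tr$mask == 1))
    expect_gt(agree, 0.99)
  }
})

test_that("masks stay strictly binary through augmentation", {
  set.seed(13)
  img <- matrix(runif(48 * 48), 48, 48)
  msk <- matrix(as.integer(runif(48 * 48) < 0.3), 48, 48)
  for (i in 1:5) {
    a <- augment_patch_pair(img, msk)
    expect_true(all(a$mask %in% c(0L, 1L)))
    expect_equal(dim(a$img), dim(img))
  }
})

test_that("augmentation is reproducible under a fixed RNG state", {
  img <- matrix(runif(32 * 32), 32, 32)
  msk <- matrix(as.integer(runif(32 * 32) < 0.2), 32, 32)
  set.seed(99); a1 <- augment_patch_pair(img, msk)
  set.seed(99); a2 <- augment_patch_pair(img, msk)
  expect_identical(a1, a2)
})

test_that("mismatched patch pairs are rejected", {
  expect_error(transform_patch_pair(matrix(0, 4, 4), matrix(0L, 5, 5)),
               "identical dimensions")
})
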