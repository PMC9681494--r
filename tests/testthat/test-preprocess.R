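# Contrast-enhancement chain.

test_that("background zeroing blanks the margins and keeps the disc", {
  # gray margins around a bright disc: zeroing must recover the disc
  H <- 96
  di <- outer(1:H - 48.5, rep(1, H)); dj <- t(di)
  disc <- (di^2 + dj^2) <= 40^2
  img <- array(0.2, c(H, H, 3))
  for (ch in 1:3) img[, , ch][disc] <- 0.8
  z <- zero_background(img)
  for (ch in 1:3) {
    expect_true(all(z[, , ch][!attr(z, "disc")] == 0))
    expect_equal(z[, , ch][disc], img[, , ch][disc])
  }
  # detected disc matches the constructed one closely
  expect_gt(sum(attr(z, "disc") & disc) / sum(attr(z, "disc") | disc), 0.98)
})

test_that("background zeroing is idempotent and warns on empty images", {
  g <- generate_fundus_image(tiny_spec(c(MA = 2, EX = 1, HEM = 1), seed = 3))
  z1 <- zero_background(g$image)
  z2 <- zero_background(z1)
  expect_identical(z1$data, z2$data)
  black <- array(0, c(64, 64, 3))
  expect_warning(out <- zero_background(black), "no above-threshold")
  expect_identical(out, black)
})

test_that("green channel extraction returns exactly the G plane", {
  img <- array(0, c(10, 10, 3)); img[, , 2] <- 200 / 255
  expect_equal(green_channel(img), matrix(200 / 255, 10, 10))
  img2 <- array(0, c(10, 10, 3)); img2[, , 1] <- 200 / 255
  expect_equal(green_channel(img2), matrix(0, 10, 10))
  set.seed(1)
  img3 <- array(runif(300), c(10, 10, 3))
  expect_equal(green_channel(img3), img3[, , 2])
  expect_error(green_channel(matrix(0, 10, 10)), "3-channel")
})

test_that("CLAHE preserves shape, maps constants to constants, expands contrast", {
  x <- matrix(0.5, 64, 64)
  y <- clahe_enhance(x)
  expect_equal(dim(y), dim(x))
  expect_equal(length(unique(as.vector(y))), 1)  # one gray level in, one out
  # low-contrast two-level image gains dynamic range
  set.seed(2)
  lo <- matrix(0.45, 64, 64)
  lo[20:40, 20:40] <- 0.55
  hi <- clahe_enhance(lo)
  expect_gte(diff(range(hi)), diff(range(lo)))
  expect_true(all(hi >= 0 & hi <= 1))
  expect_error(clahe_enhance(matrix(0.5, 10, 10)), "too small")
})

test_that("gamma correction follows 255*(v/255)^g with fixed endpoints", {
  grid <- matrix(c(0, 64, 255) / 255, 1)
  out <- gamma_correct(grid, 0.8)
  expect_equal(out[1], 0)
  expect_equal(out[2], 84 / 255)   # 255*(64/255)^0.8 = 84.4 -> 84
  expect_equal(out[3], 1)
  x <- matrix(seq(0, 1, length.out = 256), 16, 16)
  expect_equal(gamma_correct(x, 1), quantize8(x))
  expect_error(gamma_correct(x, 0), "positive")
  expect_error(gamma_correct(x, -2), "positive")
  # gamma < 1 never decreases an 8-bit value; map is monotone
  v <- quantize8(matrix(runif(256), 16, 16))
  w <- gamma_correct(v, 0.8)
  expect_true(all(w >= v))
  sv <- sort(unique(as.vector(v)))
  expect_true(all(diff(gamma_correct(matrix(sv, 1), 0.8)) >= 0))
})

test_that("the enhancement chain composes the four steps in order", {
  g <- generate_fundus_image(tiny_spec(c(MA = 2, EX = 2, HEM = 1), seed = 4))
  e <- enhance(g$image)
  expect_s3_class(e, "enhanced_image")
  expect_equal(vapply(e$steps, `[[`, "", "op"),
               c("background_zeroed", "green", "clahe", "gamma"))
  expect_equal(dim(e$data), dim(g$image$data)[1:2])
  # margins outside the generator's disc stay exactly zero
  expect_true(all(e$data[!g$disc] == 0))
  # manual composition reproduces the chain
  z <- zero_background(g$image)
  manual <- gamma_correct(clahe_enhance(green_channel(z)), 0.8)
  manual[!attr(z, "disc")] <- 0
  expect_equal(e$data, manual)
})

test_that("every enhancement operator preserves image dimensions", {
  g <- generate_fundus_image(tiny_spec(seed = 8))
  x <- g$image$data
  expect_equal(dim(zero_background(x))[1:2], dim(x)[1:2])
  expect_equal(dim(green_channel(x)), dim(x)[1:2])
  expect_equal(dim(clahe_enhance(green_channel(x))), dim(x)[1:2])
  expect_equal(dim(gamma_correct(green_channel(x))), dim(x)[1:2])
})
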