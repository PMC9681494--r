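# The compiled convolution engine against plain-R oracles.

direct_conv <- function(x, W, b, k, stride, pad) {
  # naive direct convolution, double precision
  H <- dim(x)[1]; Wd <- dim(x)[2]; Cin <- dim(x)[3]
  Cout <- ncol(W)
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (Wd + 2 * pad - k) %/% stride + 1
  out <- array(0, c(Ho, Wo, Cout))
  for (co in seq_len(Cout)) {
    for (i in seq_len(Ho)) {
      for (j in seq_len(Wo)) {
        acc <- b[co]
        for (c in seq_len(Cin)) {
          for (kj in 0:(k - 1)) {
            for (ki in 0:(k - 1)) {
              si <- (i - 1) * stride - pad + ki + 1
              sj <- (j - 1) * stride - pad + kj + 1
              if (si >= 1 && si <= H && sj >= 1 && sj <= Wd) {
                f <- ki + k * kj + k * k * (c - 1) + 1
                acc <- acc + x[si, sj, c] * W[f, co]
              }
            }
          }
        }
        out[i, j, co] <- acc
      }
    }
  }
  out
}

test_that("convolution forward matches a direct-loop oracle", {
  set.seed(1)
  for (case in list(list(k = 3, s = 1, p = 1, H = 8, C = 2, Co = 3),
                    list(k = 1, s = 1, p = 0, H = 6, C = 4, Co = 2),
                    list(k = 7, s = 2, p = 3, H = 12, C = 1, Co = 2),
                    list(k = 3, s = 2, p = 1, H = 9, C = 2, Co = 2))) {
    x <- array(rnorm(case$H^2 * case$C), c(case$H, case$H, case$C))
    W <- matrix(rnorm(case$k^2 * case$C * case$Co), case$k^2 * case$C)
    b <- rnorm(case$Co)
    got <- drdetect:::cn_conv_fwd(x, W, b, case$k, case$s, case$p)
    want <- direct_conv(x, W, b, case$k, case$s, case$p)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("batched convolution equals per-item convolution", {
  set.seed(2)
  B <- 3
  xs <- lapply(1:B, function(i) array(rnorm(8 * 8 * 2), c(8, 8, 2)))
  W <- matrix(rnorm(9 * 2 * 4), 18); b <- rnorm(4)
  xb <- array(unlist(xs), c(8, 8, 2, B))
  yb <- drdetect:::cnb_conv_fwd(xb, W, b, 3L, 1L, 1L)
  for (i in 1:B) {
    yi <- drdetect:::cn_conv_fwd(xs[[i]], W, b, 3L, 1L, 1L)
    expect_equal(yb[, , , i], yi, tolerance = 1e-6)
  }
})

test_that("max pooling keeps the window maximum and routes gradients back", {
  x <- array(0, c(4, 4, 1))
  x[, , 1] <- matrix(1:16, 4, 4)
  mp <- drdetect:::cn_maxpool_fwd(x, 2L, 2L, 0L)
  expect_equal(mp$y[, , 1], matrix(c(6, 8, 14, 16), 2, 2))
  dy <- array(1, c(2, 2, 1))
  dx <- drdetect:::cn_maxpool_bwd(mp$idx, dy, 4L, 4L, 1L)
  expect_equal(sum(dx), 4)            # each output routes one unit
  expect_equal(dx[2, 2, 1], 1)        # to the argmax position
  expect_equal(dx[1, 1, 1], 0)
})

test_that("transposed convolution doubles resolution with the right taps", {
  set.seed(3)
  x <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  W <- matrix(rnorm(2 * 4 * 2), 2)  # Cin=2, Cout=2
  b <- c(0.1, -0.2)
  y <- drdetect:::cn_upconv_fwd(x, W, b)
  expect_equal(dim(y), c(6L, 6L, 2L))
  # tap t = di + 2*dj owns columns t*Cout + (1:Cout)
  for (t in 0:3) {
    di <- t %% 2; dj <- t %/% 2
    want <- matrix(x, 9, 2) %*% W[, t * 2 + (1:2)]
    got <- y[seq(1 + di, 6, 2), seq(1 + dj, 6, 2), ]
    expect_equal(matrix(got, 9, 2), sweep(want, 2, b, "+"),
                 tolerance = 1e-6)
  }
})

test_that("8-connected labeling joins diagonal chains; 4-connected does not", {
  m <- matrix(0L, 5, 5)
  m[cbind(1:4, 1:4)] <- 1L     # diagonal chain
  lab <- drdetect:::cn_label8(m)
  expect_equal(max(lab), 1L)
  m2 <- matrix(0L, 5, 5); m2[1, 1] <- 1L; m2[5, 5] <- 1L
  expect_equal(max(drdetect:::cn_label8(m2)), 2L)
})

test_that("border flood fill closes ring interiors but not open arcs", {
  ring <- matrix(0L, 9, 9)
  ring[3, 3:7] <- 1L; ring[7, 3:7] <- 1L; ring[3:7, 3] <- 1L
  ring[3:7, 7] <- 1L
  filled <- drdetect:::cn_fill_closed(ring)
  expect_equal(filled[5, 5], 1L)   # enclosed interior filled
  expect_equal(filled[1, 1], 0L)
  arc <- ring; arc[3, 5] <- 0L; arc[4:6, 4:6] <- 0L
  arc_f <- drdetect:::cn_fill_closed(arc)
  expect_equal(sum(arc_f), sum(arc))  # leaky ring stays unfilled
})

test_that("native training step reproduces the R-path loss and gradients", {
  cfg <- seg_config(n = 16, base_filters = 2, batch_size = 2, epochs = 1,
                    k_folds = 2, seed = 3)
  m <- build_unet(cfg)
  set.seed(4)
  xb <- array(runif(16 * 16 * 2), dim = c(16, 16, 1, 2))
  yb <- array(rbinom(512, 1, 0.3), dim = c(16, 16, 1, 2))
  st <- drdetect:::cnu_step(m$params, xb, yb, 2, 0.25)
  fw <- drdetect:::unet_forward(m, xb, keep_cache = TRUE)
  expect_equal(st$loss, focal_loss(fw$p, yb[, , 1, ], 2, 0.25),
               tolerance = 1e-6)
  dz <- array(drdetect:::focal_grad_logit(fw$p, yb[, , 1, ], 2, 0.25),
              dim = c(16, 16, 1, 2))
  gR <- drdetect:::unet_backward(m, fw$cache, dz)
  for (nm in names(gR))
    expect_equal(st$grads[[nm]], gR[[nm]], tolerance = 1e-6)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- seg_config(n = 16, base_filters = 2, batch_size = 1, epochs = 1,
                    k_folds = 2, seed = 3)
  m <- build_unet(cfg)
  set.seed(4)
  xb <- array(runif(256), dim = c(16, 16, 1, 1))
  yb <- array(rbinom(256, 1, 0.3), dim = c(16, 16, 1, 1))
  st <- drdetect:::cnu_step(m$params, xb, yb, 2, 0.25)
  loss_at <- function(mm)
    drdetect:::cnu_step(mm$params, xb, yb, 2, 0.25)$loss
  set.seed(5)
  for (nm in c("e1.c1.W", "e3.c2.W", "d2.up.W", "out.W")) {
    w <- m$params[[nm]]
    i <- sample(length(w), 1)
    eps <- 1e-3
    m1 <- m; m1$params[[nm]][i] <- w[i] + eps
    m2 <- m; m2$params[[nm]][i] <- w[i] - eps
    num <- (loss_at(m1) - loss_at(m2)) / (2 * eps)
    ana <- st$grads[[nm]][i]
    # float32 forward: compare with mixed absolute/relative tolerance
    expect_lt(abs(num - ana), 5e-2 * max(abs(num), abs(ana), 2e-4))
  }
})
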