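# U-Net architecture contracts, focal loss, and the training protocol.

test_that("configuration enforces the fixed architecture constraints", {
  expect_error(seg_config(n = 100), "divisible by 16")
  expect_error(seg_config(depth = 4), "5 convolution blocks")
  cfg <- seg_config(n = 128)
  expect_equal(cfg$depth, 5L)
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$epochs, 3L)
  expect_equal(cfg$k_folds, 5L)
  expect_equal(cfg$patch_stride, 64L)
})

test_that("the model maps n x n patches to n x n probabilities in [0,1]", {
  for (n in c(128L, 64L)) {
    cfg <- seg_config(n = n, base_filters = 2, seed = 5)
    m <- build_unet(cfg)
    set.seed(6)
    p <- predict_patch(m, matrix(runif(n * n), n, n))
    expect_equal(dim(p), c(n, n))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("an untrained model starts near the configured foreground prior", {
  cfg <- seg_config(n = 32, base_filters = 4, seed = 5, fg_prior = 0.02)
  m <- build_unet(cfg)
  p <- predict_patch(m, matrix(0.5, 32, 32))
  expect_lt(mean(p), 0.3)
})

test_that("model building is seed-deterministic", {
  cfg <- seg_config(n = 32, base_filters = 4, seed = 11)
  expect_identical(build_unet(cfg)$params, build_unet(cfg)$params)
  cfg2 <- seg_config(n = 32, base_filters = 4, seed = 12)
  expect_false(identical(build_unet(cfg)$params, build_unet(cfg2)$params))
})

test_that("focal loss matches its scalar closed form", {
  expect_lt(focal_loss(1 - 1e-9, 1), 1e-10)
  expect_equal(focal_loss(0.5, 1, gamma = 2, alpha = 0.25),
               0.25 * 0.25 * log(2), tolerance = 1e-12)  # ~0.0433
  # gamma = 0, alpha = 0.5 reduces to half the binary cross-entropy
  set.seed(7)
  p <- runif(50, 0.05, 0.95); y <- rbinom(50, 1, 0.5)
  bce <- mean(-y * log(p) - (1 - y) * log(1 - p))
  expect_equal(focal_loss(p, y, gamma = 0, alpha = 0.5), bce / 2,
               tolerance = 1e-12)
  # clamping keeps extreme predictions finite
  expect_true(is.finite(focal_loss(c(0, 1), c(1, 0))))
})

test_that("inference is deterministic and shape-preserving on full images", {
  cfg <- seg_config(n = 32, base_filters = 2, patch_stride = 16, seed = 8)
  m <- build_unet(cfg)
  set.seed(9)
  img <- matrix(runif(80 * 96), 80, 96)
  m1 <- predict_image(m, img)
  m2 <- predict_image(m, img)
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(80, 96))
  expect_true(all(m1 >= 0 & m1 <= 1))
  expect_error(predict_image(m, matrix(0, 20, 20)), "smaller")
})

test_that("training lowers the focal loss on a separable toy problem", {
  set.seed(30)
  patches <- list(); masks <- list()
  for (i in 1:24) {
    msk <- matrix(0L, 32, 32)
    ci <- sample(8:24, 1); cj <- sample(8:24, 1)
    di <- outer(1:32 - ci, rep(1, 32)); dj <- outer(rep(1, 32), 1:32 - cj)
    msk[di^2 + dj^2 <= 16] <- 1L
    patches[[i]] <- 0.3 + 0.5 * msk + matrix(rnorm(1024, 0, 0.02), 32, 32)
    masks[[i]] <- msk
  }
  cfg <- seg_config(n = 32, base_filters = 4, batch_size = 8, epochs = 4,
                    k_folds = 2, lr = 1e-3, seed = 31, augment_prob = 0)
  m <- train_unet(build_unet(cfg), patches, masks, cfg)
  tr <- attr(m, "loss_trace")
  expect_equal(length(tr), 4)
  expect_lt(tr[4], tr[1])
})

test_that("cross-validation partitions patches into equal folds", {
  set.seed(32)
  patches <- lapply(1:160, function(i) matrix(runif(256), 16, 16))
  masks <- lapply(1:160, function(i)
    matrix(as.integer(runif(256) < 0.1), 16, 16))
  cfg <- seg_config(n = 16, base_filters = 2, batch_size = 32, epochs = 1,
                    k_folds = 5, seed = 33, augment_prob = 0)
  cv <- train_seg_cv(patches, masks, cfg)
  expect_equal(cv$metrics$n_val, rep(32, 5))
  expect_length(cv$models, 5)
  expect_true(cv$best_fold %in% 1:5)
  expect_s3_class(cv$model, "seg_model")
  # too few patches for the protocol is an error
  expect_error(train_seg_cv(patches[1:100], masks[1:100], cfg), "at least")
})

test_that("image-grouped folds never split one image across folds", {
  set.seed(34)
  patches <- lapply(1:160, function(i) matrix(runif(256), 16, 16))
  masks <- lapply(1:160, function(i)
    matrix(as.integer(runif(256) < 0.1), 16, 16))
  group <- rep(1:20, each = 8)
  cfg <- seg_config(n = 16, base_filters = 2, batch_size = 32, epochs = 1,
                    k_folds = 5, seed = 35, augment_prob = 0)
  cv <- train_seg_cv(patches, masks, cfg, group = group)
  expect_equal(sum(cv$metrics$n_val), 160)
  expect_true(all(cv$metrics$n_val %% 8 == 0))
})

test_that("models survive a save/load round trip with a JSON sidecar", {
  cfg <- seg_config(n = 32, base_filters = 2, seed = 36, lesion_class = "EX")
  m <- build_unet(cfg)
  f <- tempfile(fileext = ".rds")
  save_seg_model(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  m2 <- load_seg_model(f)
  set.seed(37)
  x <- matrix(runif(1024), 32, 32)
  expect_identical(predict_patch(m, x), predict_patch(m2, x))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$n, 32)
  expect_equal(side$lesion_class, "EX")
})
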