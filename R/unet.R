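#' Segmentation model configuration
#'
#' Holds the architecture and training protocol of one per-lesion binary
#' segmentation model: patch size `n` (128 for MA due to small lesion size,
#' 256 for EX/HEM), 5 convolution blocks on each path, batch size 32,
#' 3 epochs, 5-fold cross-validation, and a binary focal loss against the
#' strong foreground/background class imbalance.
#'
#' @param n Patch side in pixels; must be divisible by 16 (four poolings
#'   between the five encoder blocks).
#' @param base_filters Filters in the first encoder block; doubled per
#'   block (use 8 or less for CPU-scale runs).
#' @param depth Number of encoder blocks (fixed at 5).
#' @param batch_size Training batch size (default 32).
#' @param epochs Training epochs per fold (default 3).
#' @param k_folds Cross-validation folds (default 5).
#' @param focal_gamma,focal_alpha Focal-loss parameters (canonical 2, 0.25).
#' @param lr Adam learning rate.
#' @param patch_stride Tiling stride; default `n/2` (50% overlap).
#' @param augment_prob Probability that a training patch is augmented in a
#'   given pass (flips + full-circle rotation).
#' @param seed Integer seed controlling initialization, fold assignment,
#'   batching and augmentation.
#' @param fg_prior Assumed foreground fraction used to initialize the
#'   output-layer bias at its prior logit, so training starts from the
#'   correct class prior instead of spending early steps learning it
#'   (standard practice for heavily imbalanced dense prediction).
#' @param lesion_class Optional class tag (`"MA"`, `"EX"`, `"HEM"`).
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(n = 256, base_filters = 16, depth = 5,
                       batch_size = 32, epochs = 3, k_folds = 5,
                       focal_gamma = 2, focal_alpha = 0.25, lr = 1e-3,
                       patch_stride = n %/% 2, augment_prob = 0.5,
                       seed = 1L, fg_prior = 0.02,
                       lesion_class = NA_character_) {
  if (depth != 5) stop("the architecture uses exactly 5 convolution blocks")
  if (n %% 16 != 0) stop("patch size n must be divisible by 16")
  if (fg_prior <= 0 || fg_prior >= 1) stop("fg_prior must be in (0, 1)")
  structure(list(n = as.integer(n), base_filters = as.integer(base_filters),
                 depth = 5L, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), k_folds = as.integer(k_folds),
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha,
                 lr = lr, patch_stride = as.integer(patch_stride),
                 augment_prob = augment_prob, seed = as.integer(seed),
                 fg_prior = fg_prior, lesion_class = lesion_class),
            class = "seg_config")
}

.he_mat <- function(nin, nout, fan_in) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / fan_in)), nin, nout)
}

#' Build an untrained U-Net segmentation model
#'
#' Symmetric encoder–decoder: five encoder blocks of two 3x3 "same"
#' convolutions (ReLU) with 2x2 max pooling between them, and a decoder of
#' 2x2 transposed convolutions (ReLU) each followed by concatenation with
#' the matching encoder output (skip connection) and two 3x3 convolutions.
#' A 1x1 sigmoid output layer emits a per-pixel foreground probability.
#' Weights are He-initialized from `cfg$seed`.
#'
#' @param cfg A [seg_config()].
#' @return An object of class `seg_model` with elements `params` (flat
#'   named list of weight matrices), `cfg` and `lesion_class`.
#' @export
build_unet <- function(cfg) {
  stopifnot(inherits(cfg, "seg_config"))
  ch <- cfg$base_filters * 2^(0:4)
  with_seed(cfg$seed, {
    p <- list()
    cin <- 1L
    for (i in 1:5) {
      p[[sprintf("e%d.c1.W", i)]] <- .he_mat(9 * cin, ch[i], 9 * cin)
      p[[sprintf("e%d.c1.b", i)]] <- numeric(ch[i])
      p[[sprintf("e%d.c2.W", i)]] <- .he_mat(9 * ch[i], ch[i], 9 * ch[i])
      p[[sprintf("e%d.c2.b", i)]] <- numeric(ch[i])
      cin <- ch[i]
    }
    for (i in 4:1) {
      p[[sprintf("d%d.up.W", i)]] <- .he_mat(ch[i + 1], 4 * ch[i], ch[i + 1])
      p[[sprintf("d%d.up.b", i)]] <- numeric(ch[i])
      p[[sprintf("d%d.c1.W", i)]] <- .he_mat(9 * 2 * ch[i], ch[i],
                                             9 * 2 * ch[i])
      p[[sprintf("d%d.c1.b", i)]] <- numeric(ch[i])
      p[[sprintf("d%d.c2.W", i)]] <- .he_mat(9 * ch[i], ch[i], 9 * ch[i])
      p[[sprintf("d%d.c2.b", i)]] <- numeric(ch[i])
    }
    p[["out.W"]] <- .he_mat(ch[1], 1, ch[1])
    fp <- cfg$fg_prior %||% 0.02
    p[["out.b"]] <- log(fp / (1 - fp))
    structure(list(params = p, cfg = cfg, lesion_class = cfg$lesion_class),
              class = "seg_model")
  })
}

#' @export
print.seg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("seg_model (%s): n=%d, base_filters=%d, %d parameters\n",
              x$lesion_class, x$cfg$n, x$cfg$base_filters, np))
  invisible(x)
}

.relu <- function(x) { x[x < 0] <- 0; x }
.sigmoid <- function(z) 1 / (1 + exp(-z))
# concatenate two (H, W, C, B) activations along the channel axis
.cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# stack a list of n x n matrices into an (n, n, 1, B) batch array
.stack_patches <- function(patches, n) {
  array(unlist(patches, use.names = FALSE), dim = c(n, n, 1, length(patches)))
}

# Forward pass on a batch: x is (n, n, 1, B). Returns list(p, cache).
unet_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  n <- model$cfg$n
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1, 1))
  if (!all(dim(x)[1:2] == n)) stop("patch size mismatch with model")
  a <- x
  cache <- if (keep_cache) new.env(parent = emptyenv()) else NULL
  enc <- vector("list", 5)
  for (i in 1:5) {
    inp <- a
    h1 <- .relu(cnb_conv_fwd(inp, p[[sprintf("e%d.c1.W", i)]],
                             p[[sprintf("e%d.c1.b", i)]], 3L, 1L, 1L))
    h2 <- .relu(cnb_conv_fwd(h1, p[[sprintf("e%d.c2.W", i)]],
                             p[[sprintf("e%d.c2.b", i)]], 3L, 1L, 1L))
    enc[[i]] <- h2
    if (keep_cache) {
      cache[[sprintf("e%d.in", i)]] <- inp
      cache[[sprintf("e%d.h1", i)]] <- h1
    }
    if (i < 5) {
      mp <- cnb_maxpool_fwd(h2, 2L, 2L, 0L)
      a <- mp$y
      if (keep_cache) cache[[sprintf("e%d.poolidx", i)]] <- mp$idx
    }
  }
  d <- enc[[5]]
  for (i in 4:1) {
    u <- .relu(cnb_upconv_fwd(d, p[[sprintf("d%d.up.W", i)]],
                              p[[sprintf("d%d.up.b", i)]]))
    ct <- .cat_ch(enc[[i]], u)
    h1 <- .relu(cnb_conv_fwd(ct, p[[sprintf("d%d.c1.W", i)]],
                             p[[sprintf("d%d.c1.b", i)]], 3L, 1L, 1L))
    h2 <- .relu(cnb_conv_fwd(h1, p[[sprintf("d%d.c2.W", i)]],
                             p[[sprintf("d%d.c2.b", i)]], 3L, 1L, 1L))
    if (keep_cache) {
      cache[[sprintf("d%d.in", i)]] <- d
      cache[[sprintf("d%d.u", i)]] <- u
      cache[[sprintf("d%d.cat", i)]] <- ct
      cache[[sprintf("d%d.h1", i)]] <- h1
      cache[[sprintf("d%d.h2", i)]] <- h2
    }
    d <- h2
  }
  z <- cnb_conv_fwd(d, p[["out.W"]], p[["out.b"]], 1L, 1L, 0L)
  if (keep_cache) {
    cache[["enc"]] <- enc
    cache[["top"]] <- d
  }
  list(p = .sigmoid(z[, , 1, ]), z = z, cache = cache)
}

# Backward pass: dz is dL/dlogits as an (n, n, 1, B) array.
# Returns a flat named list of gradients matching model$params.
unet_backward <- function(model, cache, dz) {
  p <- model$params
  g <- list()
  enc <- cache[["enc"]]
  bw <- cnb_conv_bwd(cache[["top"]], p[["out.W"]], dz, 1L, 1L, 0L)
  g[["out.W"]] <- bw$dW; g[["out.b"]] <- bw$db
  dd <- bw$dx
  denc <- vector("list", 5)  # gradient wrt each encoder block output
  for (i in 1:4) {
    h2 <- cache[[sprintf("d%d.h2", i)]]
    dd[h2 <= 0] <- 0
    bw <- cnb_conv_bwd(cache[[sprintf("d%d.h1", i)]],
                       p[[sprintf("d%d.c2.W", i)]], dd, 3L, 1L, 1L)
    g[[sprintf("d%d.c2.W", i)]] <- bw$dW
    g[[sprintf("d%d.c2.b", i)]] <- bw$db
    dh1 <- bw$dx
    dh1[cache[[sprintf("d%d.h1", i)]] <= 0] <- 0
    bw <- cnb_conv_bwd(cache[[sprintf("d%d.cat", i)]],
                       p[[sprintf("d%d.c1.W", i)]], dh1, 3L, 1L, 1L)
    g[[sprintf("d%d.c1.W", i)]] <- bw$dW
    g[[sprintf("d%d.c1.b", i)]] <- bw$db
    nskip <- dim(enc[[i]])[3]
    dct <- bw$dx
    denc[[i]] <- dct[, , seq_len(nskip), , drop = FALSE]
    du <- dct[, , nskip + seq_len(dim(dct)[3] - nskip), , drop = FALSE]
    du[cache[[sprintf("d%d.u", i)]] <= 0] <- 0
    bw <- cnb_upconv_bwd(cache[[sprintf("d%d.in", i)]],
                         p[[sprintf("d%d.up.W", i)]], du)
    g[[sprintf("d%d.up.W", i)]] <- bw$dW
    g[[sprintf("d%d.up.b", i)]] <- bw$db
    dd <- bw$dx
  }
  denc[[5]] <- dd
  for (i in 5:1) {
    da2 <- denc[[i]]
    da2[enc[[i]] <= 0] <- 0
    bw <- cnb_conv_bwd(cache[[sprintf("e%d.h1", i)]],
                       p[[sprintf("e%d.c2.W", i)]], da2, 3L, 1L, 1L)
    g[[sprintf("e%d.c2.W", i)]] <- bw$dW
    g[[sprintf("e%d.c2.b", i)]] <- bw$db
    dh1 <- bw$dx
    dh1[cache[[sprintf("e%d.h1", i)]] <= 0] <- 0
    bw <- cnb_conv_bwd(cache[[sprintf("e%d.in", i)]],
                       p[[sprintf("e%d.c1.W", i)]], dh1, 3L, 1L, 1L)
    g[[sprintf("e%d.c1.W", i)]] <- bw$dW
    g[[sprintf("e%d.c1.b", i)]] <- bw$db
    if (i > 1) {
      din <- bw$dx
      below <- cache[[sprintf("e%d.in", i)]]
      prev <- enc[[i - 1]]
      dpool <- cnb_maxpool_bwd(cache[[sprintf("e%d.poolidx", i - 1)]], din,
                               dim(prev)[1], dim(prev)[2], dim(prev)[3],
                               dim(prev)[4])
      denc[[i - 1]] <- denc[[i - 1]] + dpool
    }
  }
  g
}

#' Binary focal loss
#'
#' Per-pixel loss `alpha * (1-p)^gamma * (-log p)` for foreground pixels
#' and `(1-alpha) * p^gamma * (-log(1-p))` for background, averaged over
#' all pixels. With `gamma = 0`, `alpha = 0.5` this reduces to half the
#' standard binary cross-entropy. Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param p Predicted probabilities in \eqn{[0,1]} (any numeric shape).
#' @param y Ground-truth labels in `{0, 1}`, same shape.
#' @param gamma Focusing parameter (default 2).
#' @param alpha Foreground balance weight (default 0.25).
#' @return Non-negative scalar loss.
#' @export
focal_loss <- function(p, y, gamma = 2, alpha = 0.25) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  lpos <- alpha * (1 - p)^gamma * (-log(p))
  lneg <- (1 - alpha) * p^gamma * (-log(1 - p))
  mean(ifelse(y == 1, lpos, lneg))
}

# dL/dz for z the logit (p = sigmoid(z)); averaged over pixels.
focal_grad_logit <- function(p, y, gamma = 2, alpha = 0.25) {
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  dldp_pos <- alpha * (gamma * (1 - pc)^(gamma - 1) * log(pc) -
                         (1 - pc)^gamma / pc)
  dldp_neg <- (1 - alpha) * (gamma * pc^(gamma - 1) * (-log(1 - pc)) +
                               pc^gamma / (1 - pc))
  dldp <- ifelse(y == 1, dldp_pos, dldp_neg)
  dldp * pc * (1 - pc) / length(p)
}

.adam_init <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0), t = 0)
}

.adam_step <- function(params, grads, st, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(params)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * grads[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

#' Train a U-Net on image/mask patch pairs
#'
#' Adam on the binary focal loss. Steps per epoch equal the number of
#' training patches divided by the batch size; each patch is augmented
#' (random flip, random full-circle rotation) with probability
#' `cfg$augment_prob` in each pass.
#'
#' @param model A [build_unet()] model.
#' @param patches List of `n x n` image patches (values in \eqn{[0,1]}).
#' @param masks List of matching 0/1 mask patches.
#' @param cfg A [seg_config()]; `NULL` uses the model's own.
#' @param verbose Print per-epoch mean loss.
#' @return The trained `seg_model`, with the loss trace in
#'   `attr(, "loss_trace")`.
#' @export
train_unet <- function(model, patches, masks, cfg = NULL, verbose = FALSE) {
  cfg <- cfg %||% model$cfg
  stopifnot(length(patches) == length(masks), length(patches) > 0)
  params <- model$params
  st <- .adam_init(params)
  steps <- max(1L, length(patches) %/% cfg$batch_size)
  trace <- numeric(0)
  for (ep in seq_len(cfg$epochs)) {
    idx <- sample(length(patches))
    ep_loss <- 0
    for (s in seq_len(steps)) {
      take <- idx[((s - 1) * cfg$batch_size + 1):
                    min(s * cfg$batch_size, length(idx))]
      xs <- patches[take]; ys <- masks[take]
      aug_sel <- runif(length(take)) < cfg$augment_prob
      for (t in which(aug_sel)) {
        aug <- augment_patch_pair(xs[[t]], ys[[t]])
        xs[[t]] <- aug$img; ys[[t]] <- aug$mask
      }
      xb <- .stack_patches(xs, cfg$n)
      yb <- .stack_patches(ys, cfg$n)
      # single native call: forward, focal loss (mean over batch pixels,
      # so gradients are batch means), backward
      fw <- cnu_step(params, xb, yb, cfg$focal_gamma, cfg$focal_alpha)
      upd <- .adam_step(params, fw$grads, st, cfg$lr)
      params <- upd$params; st <- upd$state
      ep_loss <- ep_loss + fw$loss
    }
    trace <- c(trace, ep_loss / steps)
    if (verbose)
      message(sprintf("epoch %d/%d: focal loss %.5f", ep, cfg$epochs,
                      trace[length(trace)]))
  }
  model$params <- params
  attr(model, "loss_trace") <- trace
  model
}

#' Predict the probability map of a single patch
#'
#' @param model A `seg_model`.
#' @param patch `n x n` matrix in \eqn{[0,1]}.
#' @return `n x n` matrix of foreground probabilities in \eqn{[0,1]}.
#' @export
predict_patch <- function(model, patch) {
  unet_forward(model, patch)$p
}

#' Batch-predict probability maps for a list of patches
#'
#' @param model A trained `seg_model`.
#' @param patches List of `n x n` matrices.
#' @param chunk Patches per forward pass (memory/speed trade-off).
#' @return List of `n x n` probability maps.
#' @export
predict_patches <- function(model, patches, chunk = 16L) {
  n <- model$cfg$n
  out <- vector("list", length(patches))
  for (s in seq(1, length(patches), by = chunk)) {
    take <- s:min(s + chunk - 1, length(patches))
    pb <- cnu_predict(model$params, .stack_patches(patches[take], n))
    for (t in seq_along(take)) out[[take[t]]] <- pb[, , 1, t]
  }
  out
}

#' Predict a full-resolution probability map for an image
#'
#' Tiles the enhanced image with the model's patch size, batch-predicts
#' every patch, and merges the patch probability maps back into a map with
#' the dimensions of the input image.
#'
#' @param model A trained `seg_model`.
#' @param img An `enhanced_image` (see [enhance()]) or `H x W` matrix.
#' @param stride Tiling stride; defaults to the model's `patch_stride`.
#' @return `H x W` probability map in \eqn{[0,1]}.
#' @export
predict_image <- function(model, img, stride = NULL) {
  x <- if (inherits(img, "enhanced_image")) img$data else img
  n <- model$cfg$n
  if (min(dim(x)) < n)
    stop(sprintf("image (%dx%d) smaller than patch size %d",
                 nrow(x), ncol(x), n))
  stride <- stride %||% model$cfg$patch_stride
  ps <- tile_patches(x, n, stride)
  maps <- predict_patches(model, ps$patches)
  reconstruct_map(maps, ps$placements, ps$H, ps$W)
}

#' K-fold cross-validated segmentation training
#'
#' Shuffles the patches (seed-controlled), partitions them into
#' `cfg$k_folds` folds, trains one model per fold on the remaining folds
#' and evaluates pixelwise metrics on the fold's validation patches. The
#' fold with the best validation accuracy is retained as the final model.
#'
#' @param patches List of `n x n` image patches.
#' @param masks Matching list of 0/1 mask patches.
#' @param cfg A [seg_config()].
#' @param group Optional grouping vector (e.g. source image index) of the
#'   same length as `patches`; when given, folds are assigned at group
#'   level so patches of one image never straddle a fold boundary.
#' @param verbose Print fold progress.
#' @return List with `model` (retained best model), `models` (all folds),
#'   `metrics` (per-fold data.frame of recall/precision/f1/accuracy/iou)
#'   and `best_fold`.
#' @export
train_seg_cv <- function(patches, masks, cfg, group = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "seg_config"))
  N <- length(patches)
  if (N < cfg$k_folds * cfg$batch_size)
    stop(sprintf("need at least k_folds * batch_size = %d patches, got %d",
                 cfg$k_folds * cfg$batch_size, N))
  with_seed(cfg$seed, {
    if (is.null(group)) {
      fold <- rep_len(seq_len(cfg$k_folds), N)[sample(N)]
    } else {
      gids <- unique(group)
      gfold <- rep_len(seq_len(cfg$k_folds), length(gids))[
        sample(length(gids))]
      fold <- gfold[match(group, gids)]
    }
    models <- vector("list", cfg$k_folds)
    rows <- vector("list", cfg$k_folds)
    for (k in seq_len(cfg$k_folds)) {
      tr <- which(fold != k); va <- which(fold == k)
      cfg_k <- cfg
      cfg_k$seed <- (cfg$seed + k) %% .Machine$integer.max
      m <- build_unet(cfg_k)
      m <- train_unet(m, patches[tr], masks[tr], cfg, verbose = verbose)
      cc <- c(TP = 0, FP = 0, FN = 0, TN = 0)
      vmaps <- predict_patches(m, patches[va])
      for (j in seq_along(va)) {
        pred <- binarize_map(vmaps[[j]])
        cc <- cc + confusion_counts(pred == 1L, masks[[va[j]]] == 1L)
      }
      if (cc[["TP"]] + cc[["FN"]] == 0)
        warning(sprintf(
          "fold %d has no foreground pixels; metrics partially undefined", k))
      met <- metrics_from_confusion(cc)
      models[[k]] <- m
      rows[[k]] <- data.frame(fold = k, recall = met$recall,
                              precision = met$precision, f1 = met$f1,
                              accuracy = met$accuracy, iou = met$iou,
                              n_val = length(va))
      if (verbose)
        message(sprintf("fold %d: acc=%.4f iou=%.4f", k,
                        met$accuracy %||% NA, met$iou %||% NA))
    }
    metrics <- do.call(rbind, rows)
    acc <- ifelse(is.na(metrics$accuracy), -Inf, metrics$accuracy)
    best <- which.max(acc)
    list(model = models[[best]], models = models, metrics = metrics,
         best_fold = best)
  })
}

#' Save / load a segmentation model
#'
#' The weights go to a single file; a JSON sidecar (`<path>.json`) records
#' the model configuration for provenance.
#'
#' @param model A `seg_model`.
#' @param path Destination file.
#' @return `save_seg_model`: `path`, invisibly. `load_seg_model`: the
#'   restored `seg_model`.
#' @export
save_seg_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(model$cfg[setdiff(names(model$cfg), NULL)],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_seg_model
#' @export
load_seg_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "seg_model"))
  m
}
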