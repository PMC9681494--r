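#' Backbone specification for deep feature extraction
#'
#' Describes a "topless" image-classification backbone: the softmax and
#' fully connected layers are removed and the activation volume of the last
#' convolutional stage is used as a generic image descriptor. VGG-16 ends
#' in a 7x7x512 volume (25,088 features when flattened); ResNet-50 ends in
#' 7x7x2048 (100,352 features). Both expect 224x224x3 input.
#'
#' ImageNet-pretrained weights require a network download, so the testable
#' default is `weights = "random"`: He-initialized weights from `seed`,
#' which preserve every architectural dimension and are fully
#' deterministic.
#'
#' @param architecture `"vgg16"` or `"resnet50"`.
#' @param weights `"random"` (default) or `"imagenet"`; the latter errors
#'   with advice unless a local weights loader is plugged in.
#' @param seed Seed for random-weight initialization.
#' @return An object of class `backbone_spec`.
#' @export
backbone_spec <- function(architecture = c("vgg16", "resnet50"),
                          weights = "random", seed = 1L) {
  architecture <- match.arg(architecture)
  if (!weights %in% c("random", "imagenet"))
    stop("weights must be 'random' or 'imagenet'")
  structure(list(architecture = architecture, weights = weights,
                 seed = as.integer(seed),
                 input_shape = c(224L, 224L, 3L),
                 terminal_volume = if (architecture == "vgg16")
                   c(7L, 7L, 512L) else c(7L, 7L, 2048L)),
            class = "backbone_spec")
}

#' Deep feature length of a backbone
#'
#' @param spec A [backbone_spec()].
#' @return Flattened feature length: 25,088 (vgg16) or 100,352 (resnet50).
#' @export
deep_feature_length <- function(spec) prod(spec$terminal_volume)

#' Resize and normalize an image for a backbone
#'
#' Bilinear resize to 224x224 and the canonical channel normalization of
#' both architectures (RGB to BGR, subtraction of the ImageNet channel
#' means on the 0–255 scale); the applied preprocessing is recorded in
#' `attr(, "preprocessing")`.
#'
#' @param img A [fundus_image()] or `H x W x 3` array in \eqn{[0,1]}.
#' @return `224 x 224 x 3` numeric array.
#' @export
prepare_backbone_input <- function(img) {
  x <- if (inherits(img, "fundus_image")) img$data else img
  if (length(dim(x)) != 3 || dim(x)[3] != 3)
    stop("backbone input must be a 3-channel RGB image")
  im <- EBImage::Image(aperm(x, c(2, 1, 3)), colormode = "Color")
  rs <- aperm(as.array(EBImage::resize(im, w = 224, h = 224)), c(2, 1, 3))
  out <- rs * 255
  out <- out[, , c(3, 2, 1)]  # RGB -> BGR
  means <- c(103.939, 116.779, 123.68)
  for (ch in 1:3) out[, , ch] <- out[, , ch] - means[ch]
  attr(out, "preprocessing") <- "bilinear-224, BGR, imagenet mean subtraction"
  out
}

# layer constructors (weights only; forward is data-driven)
.conv_layer <- function(cin, cout, k, stride, pad) {
  list(type = "conv", W = .he_mat(k * k * cin, cout, k * k * cin),
       b = numeric(cout), k = k, stride = stride, pad = pad, cout = cout)
}
.pool_layer <- function(size, stride, pad) {
  list(type = "pool", size = size, stride = stride, pad = pad)
}

.build_vgg16 <- function() {
  widths <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                 c(512, 512, 512), c(512, 512, 512))
  layers <- list()
  cin <- 3
  for (blk in widths) {
    for (cout in blk) {
      layers[[length(layers) + 1]] <- .conv_layer(cin, cout, 3, 1, 1)
      cin <- cout
    }
    layers[[length(layers) + 1]] <- .pool_layer(2, 2, 0)
  }
  layers
}

.build_resnet50 <- function() {
  stages <- list(list(n = 3, cmid = 64, stride = 1),
                 list(n = 4, cmid = 128, stride = 2),
                 list(n = 6, cmid = 256, stride = 2),
                 list(n = 3, cmid = 512, stride = 2))
  blocks <- list(list(type = "stem",
                      conv = .conv_layer(3, 64, 7, 2, 3),
                      pool = .pool_layer(3, 2, 1)))
  cin <- 64
  for (st in stages) {
    for (b in seq_len(st$n)) {
      s <- if (b == 1) st$stride else 1
      cout <- 4 * st$cmid
      blk <- list(type = "bottleneck",
                  c1 = .conv_layer(cin, st$cmid, 1, 1, 0),
                  c2 = .conv_layer(st$cmid, st$cmid, 3, s, 1),
                  c3 = .conv_layer(st$cmid, cout, 1, 1, 0),
                  proj = if (b == 1)
                    .conv_layer(cin, cout, 1, s, 0) else NULL)
      blocks[[length(blocks) + 1]] <- blk
      cin <- cout
    }
  }
  blocks
}

#' Build a topless backbone with explicit weights
#'
#' @param spec A [backbone_spec()].
#' @return An object of class `backbone` carrying the layer list; random
#'   weights are drawn deterministically from `spec$seed`.
#' @export
build_backbone <- function(spec) {
  stopifnot(inherits(spec, "backbone_spec"))
  if (spec$weights == "imagenet")
    stop("pretrained ImageNet weights are not bundled (they require a ",
         "download); use backbone_spec(weights = 'random') for ",
         "architecture-faithful random-weight extraction")
  layers <- with_seed(spec$seed, {
    if (spec$architecture == "vgg16") .build_vgg16() else .build_resnet50()
  })
  structure(list(spec = spec, layers = layers), class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("topless %s backbone (%s weights): 224x224x3 -> %s\n",
              x$spec$architecture, x$spec$weights,
              paste(x$spec$terminal_volume, collapse = "x")))
  invisible(x)
}

.forward_plain <- function(layers, a) {
  for (ly in layers) {
    if (ly$type == "conv")
      a <- .relu(cn_conv_fwd(a, ly$W, ly$b, ly$k, ly$stride, ly$pad))
    else a <- cn_maxpool_fwd(a, ly$size, ly$stride, ly$pad)$y
  }
  a
}

.forward_resnet <- function(blocks, a) {
  for (blk in blocks) {
    if (blk$type == "stem") {
      cv <- blk$conv
      a <- .relu(cn_conv_fwd(a, cv$W, cv$b, cv$k, cv$stride, cv$pad))
      a <- cn_maxpool_fwd(a, blk$pool$size, blk$pool$stride, blk$pool$pad)$y
    } else {
      sc <- if (is.null(blk$proj)) a else
        cn_conv_fwd(a, blk$proj$W, blk$proj$b, blk$proj$k, blk$proj$stride,
                    blk$proj$pad)
      h <- .relu(cn_conv_fwd(a, blk$c1$W, blk$c1$b, blk$c1$k, blk$c1$stride,
                             blk$c1$pad))
      h <- .relu(cn_conv_fwd(h, blk$c2$W, blk$c2$b, blk$c2$k, blk$c2$stride,
                             blk$c2$pad))
      h <- cn_conv_fwd(h, blk$c3$W, blk$c3$b, blk$c3$k, blk$c3$stride,
                       blk$c3$pad)
      # residual branches are scaled so activations stay well-conditioned
      # through the 16 blocks
      a <- .relu((h + sc) / sqrt(2))
    }
  }
  a
}

#' Extract flattened deep features from an image
#'
#' Propagates the prepared input through the topless backbone and flattens
#' the terminal activation volume in row-major `(row, col, channel)` order
#' (channel fastest), the order the fused feature indices rely on.
#'
#' @param img A [fundus_image()] or `H x W x 3` array.
#' @param backbone A [build_backbone()] model or a [backbone_spec()] (the
#'   backbone is then built on the fly).
#' @return Numeric `deep_feature_vector` of length 25,088 (vgg16) or
#'   100,352 (resnet50), with attributes `backbone` and `preprocessing`.
#' @export
extract_deep_features <- function(img, backbone) {
  if (inherits(backbone, "backbone_spec")) backbone <- build_backbone(backbone)
  stopifnot(inherits(backbone, "backbone"))
  a <- prepare_backbone_input(img)
  prep <- attr(a, "preprocessing")
  vol <- if (backbone$spec$architecture == "vgg16")
    .forward_plain(backbone$layers, a)
  else .forward_resnet(backbone$layers, a)
  tv <- backbone$spec$terminal_volume
  if (!all(dim(vol) == tv))
    stop(sprintf("terminal volume %s does not match expected %s",
                 paste(dim(vol), collapse = "x"),
                 paste(tv, collapse = "x")))
  v <- as.vector(aperm(vol, c(3, 2, 1)))  # channel fastest, then col, row
  attr(v, "backbone") <- backbone$spec$architecture
  attr(v, "weights") <- backbone$spec$weights
  attr(v, "preprocessing") <- prep
  class(v) <- c("deep_feature_vector", class(v))
  v
}
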