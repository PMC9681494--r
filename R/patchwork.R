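#' Anchor offsets for overlapping tiling
#'
#' Anchors advance in `stride` steps from 0 and a final anchor at
#' `len - n` is appended when the stride does not land on it, so the patch
#' footprints cover the full extent without padding.
#'
#' @param len Image extent (pixels).
#' @param n Patch size.
#' @param stride Step between anchors, `1 <= stride <= n`.
#' @return Integer vector of 0-based offsets.
#' @export
tile_anchors <- function(len, n, stride) {
  if (n > len) stop("patch size exceeds image dimension")
  if (stride < 1 || stride > n) stop("stride must be in [1, n]")
  a <- seq.int(0L, len - n, by = stride)
  if (a[length(a)] != len - n) a <- c(a, len - n)
  unique(a)
}

#' Tile an image into overlapping square patches
#'
#' @param x `H x W` matrix (an enhanced image, a mask, or a probability
#'   map).
#' @param n Patch side in pixels (128 for MA models, 256 for EX/HEM).
#' @param stride Anchor step; default `n/2` (50% overlap).
#' @return A `patch_set`: list with `patches` (list of `n x n` matrices),
#'   `placements` (integer matrix of 0-based `(row_offset, col_offset)`),
#'   and `n`, `stride`, `H`, `W`.
#' @export
tile_patches <- function(x, n, stride = n %/% 2) {
  H <- nrow(x); W <- ncol(x)
  ra <- tile_anchors(H, n, stride)
  ca <- tile_anchors(W, n, stride)
  placements <- as.matrix(expand.grid(row = ra, col = ca))
  patches <- lapply(seq_len(nrow(placements)), function(i) {
    r <- placements[i, 1]; c <- placements[i, 2]
    x[(r + 1):(r + n), (c + 1):(c + n), drop = FALSE]
  })
  structure(list(patches = patches, placements = placements, n = n,
                 stride = stride, H = H, W = W), class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set: %d patches of %dx%d (stride %d) from %dx%d\n",
              length(x$patches), x$n, x$n, x$stride, x$H, x$W))
  invisible(x)
}

# Bilinear (images) / nearest (masks) rotation about the patch center with
# reflected out-of-range sampling, so rotated corners carry image content
# instead of invented constant fill.
.reflect_index <- function(i, n) {
  # reflect into [1, n] (period 2n-2)
  i <- (i - 1) %% (2 * n - 2)
  i <- ifelse(i >= n - 1 + 1e-9, 2 * n - 2 - i, i)
  i + 1
}

.rotate_patch <- function(x, angle, bilinear = TRUE) {
  n1 <- nrow(x); n2 <- ncol(x)
  th <- angle * pi / 180
  ci <- (n1 + 1) / 2; cj <- (n2 + 1) / 2
  g <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  di <- g$i - ci; dj <- g$j - cj
  si <- ci + cos(th) * di - sin(th) * dj
  sj <- cj + sin(th) * di + cos(th) * dj
  if (bilinear) {
    i0 <- floor(si); j0 <- floor(sj)
    fi <- si - i0; fj <- sj - j0
    v00 <- x[cbind(.reflect_index(i0, n1), .reflect_index(j0, n2))]
    v10 <- x[cbind(.reflect_index(i0 + 1, n1), .reflect_index(j0, n2))]
    v01 <- x[cbind(.reflect_index(i0, n1), .reflect_index(j0 + 1, n2))]
    v11 <- x[cbind(.reflect_index(i0 + 1, n1), .reflect_index(j0 + 1, n2))]
    v <- v00 * (1 - fi) * (1 - fj) + v10 * fi * (1 - fj) +
      v01 * (1 - fi) * fj + v11 * fi * fj
  } else {
    v <- x[cbind(.reflect_index(round(si), n1), .reflect_index(round(sj), n2))]
  }
  matrix(v, n1, n2)
}

#' Apply one spatial transform to an image/mask patch pair
#'
#' The identical transform (horizontal/vertical flip, rotation by an
#' arbitrary angle) is applied to both members of the pair. Images are
#' resampled bilinearly with reflected corners; masks use nearest-neighbor
#' and are re-binarized at 0.5 so they stay strictly binary.
#'
#' @param img_patch,mask_patch `n x n` matrices of equal dimensions.
#' @param hflip,vflip Logical flips.
#' @param angle Rotation angle in degrees (counter-clockwise).
#' @return List `(img, mask)`.
#' @export
transform_patch_pair <- function(img_patch, mask_patch, hflip = FALSE,
                                 vflip = FALSE, angle = 0) {
  if (!identical(dim(img_patch), dim(mask_patch)))
    stop("image and mask patches must have identical dimensions")
  tr <- function(x, bilinear) {
    if (hflip) x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
    if (vflip) x <- x[rev(seq_len(nrow(x))), , drop = FALSE]
    if (angle %% 360 != 0) x <- .rotate_patch(x, angle, bilinear)
    x
  }
  img <- tr(img_patch, TRUE)
  msk <- tr(mask_patch * 1.0, FALSE)
  list(img = img, mask = matrix(as.integer(msk >= 0.5), nrow(msk), ncol(msk)))
}

#' Randomly augment an image/mask patch pair
#'
#' Random horizontal/vertical flip and random rotation over the full 360
#' degrees, drawn from the current RNG stream; the same transform is applied
#' to the image patch and its ground-truth mask patch.
#'
#' @param img_patch,mask_patch `n x n` matrices.
#' @return List `(img, mask)`.
#' @export
augment_patch_pair <- function(img_patch, mask_patch) {
  transform_patch_pair(img_patch, mask_patch,
                       hflip = runif(1) < 0.5,
                       vflip = runif(1) < 0.5,
                       angle = runif(1, 0, 360))
}

#' Merge patch probability maps into a full-resolution map
#'
#' Each output pixel covered by k patches receives the arithmetic mean
#' (default) or the maximum of the k patch predictions, producing a
#' probability map with the dimensions of the source image.
#'
#' @param patch_maps List of `n x n` matrices with values in \eqn{[0,1]}.
#' @param placements 0-based `(row_offset, col_offset)` matrix, as produced
#'   by [tile_patches()].
#' @param H,W Output dimensions.
#' @param merge `"mean"` (default) or `"max"`.
#' @return `H x W` matrix in \eqn{[0,1]}.
#' @export
reconstruct_map <- function(patch_maps, placements, H, W, merge = "mean") {
  merge <- match.arg(merge, c("mean", "max"))
  acc <- matrix(if (merge == "mean") 0 else -Inf, H, W)
  cnt <- matrix(0L, H, W)
  for (i in seq_along(patch_maps)) {
    p <- patch_maps[[i]]
    r <- placements[i, 1]; c <- placements[i, 2]
    ri <- (r + 1):(r + nrow(p)); ci <- (c + 1):(c + ncol(p))
    if (max(ri) > H || max(ci) > W) stop("placement outside image bounds")
    if (merge == "mean") acc[ri, ci] <- acc[ri, ci] + p
    else acc[ri, ci] <- pmax(acc[ri, ci], p)
    cnt[ri, ci] <- cnt[ri, ci] + 1L
  }
  if (any(cnt == 0L)) stop("patch placements do not cover the image")
  if (merge == "mean") acc / cnt else acc
}
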