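#' Threshold a probability map into a binary mask
#'
#' @param map `H x W` matrix with values in \eqn{[0,1]}.
#' @param threshold Foreground iff probability `>= threshold` (default 0.5,
#'   the fixed operating point used when converting reconstructed maps to
#'   masks).
#' @return 0/1 integer matrix.
#' @export
binarize_map <- function(map, threshold = 0.5) {
  if (min(map) < 0 || max(map) > 1) stop("probability map must be in [0,1]")
  matrix(as.integer(map >= threshold), nrow(map), ncol(map))
}

#' Canny edge detection
#'
#' Classic pipeline: optional Gaussian smoothing, Sobel gradients,
#' non-maximum suppression along the quantized gradient direction (plateaus
#' are kept on both sides), and hysteresis thresholding: weak edges survive
#' only in 8-connected chains that contain a strong edge.
#'
#' @param x `H x W` matrix in \eqn{[0,1]}.
#' @param sigma Gaussian smoothing sigma in pixels; `0` disables smoothing
#'   (appropriate for already-binary input).
#' @param low,high Hysteresis thresholds on the 8-bit (0–255) gradient
#'   magnitude scale; defaults 50 and 150.
#' @return Logical `H x W` edge matrix.
#' @export
canny_edges <- function(x, sigma = 1, low = 50, high = 150) {
  if (!is.matrix(x)) stop("canny_edges requires a single-channel matrix")
  if (sigma > 0)
    x <- as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(x),
                                                     sigma = sigma)))
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)      # d/d(col)
  gx <- as.matrix(EBImage::imageData(EBImage::filter2(EBImage::Image(x), kx)))
  gy <- as.matrix(EBImage::imageData(EBImage::filter2(EBImage::Image(x),
                                                      t(kx))))
  mag <- sqrt(gx^2 + gy^2) * 255
  H <- nrow(x); W <- ncol(x)
  # quantize direction to 0/45/90/135 degrees
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)
  off <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  shift <- function(m, di, dj) {
    out <- matrix(0, H, W)
    ri <- seq_len(H); ci <- seq_len(W)
    si <- ri - di; sj <- ci - dj
    ok_i <- si >= 1 & si <= H; ok_j <- sj >= 1 & sj <= W
    out[ri[ok_i], ci[ok_j]] <- m[si[ok_i], sj[ok_j]]
    out
  }
  keep <- matrix(FALSE, H, W)
  for (s in 0:3) {
    d <- off[[as.character(s)]]
    m1 <- shift(mag, d[1], d[2])
    m2 <- shift(mag, -d[1], -d[2])
    keep <- keep | (sector == s & mag >= m1 & mag >= m2)
  }
  nms <- keep & mag > 0
  weak <- nms & mag >= low
  strong <- nms & mag >= high
  if (!any(strong)) return(matrix(FALSE, H, W))
  lab <- cn_label8(matrix(as.integer(weak), H, W))
  good <- unique(lab[strong])
  matrix(lab %in% good[good > 0], H, W)
}

#' Count lesions in a binary mask by edge/contour analysis
#'
#' Canny edge detection finds the edges around mask foreground regions;
#' edge gaps are then closed (morphological closing constrained to the
#' foreground, so that distinct lesions separated by background can never
#' merge) and each fully closed shape is filled. The lesion count is the
#' number of distinct objects described by the resulting contours —
#' nested contours (a lesion with an interior hole) count once, and a
#' component cut by the image border still counts.
#'
#' @param mask 0/1 integer matrix.
#' @param min_area Optional minimum object area in pixels; the default 0
#'   counts every closed contour.
#' @return Non-negative integer lesion count.
#' @export
count_lesions <- function(mask, min_area = 0) {
  if (!all(mask %in% c(0L, 1L))) stop("count_lesions requires a binary mask")
  if (sum(mask) == 0) return(0L)
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  edges <- canny_edges(mask * 1.0, sigma = 0)
  # snap edges onto the foreground boundary and close small gaps; the
  # restriction to foreground pixels guarantees separate lesions (>= 2 px
  # apart) are never bridged
  snapped <- (EBImage::dilate(edges, EBImage::makeBrush(3, "box")) > 0) &
    (mask == 1L)
  filled <- cn_fill_closed(matrix(as.integer(snapped), nrow(mask), ncol(mask)))
  lab <- cn_label8(filled)
  if (max(lab) == 0L) return(0L)
  areas <- tabulate(lab[lab > 0])
  sum(areas >= max(min_area, 1))
}

#' Count lesions on a set of ground-truth masks
#'
#' Convenience wrapper applying [count_lesions()] per lesion class; this is
#' the oracle path that bypasses segmentation models.
#'
#' @param masks Named list of 0/1 matrices (`MA`, `EX`, `HEM`).
#' @param min_area Passed to [count_lesions()].
#' @return Named integer vector `c(MA=, EX=, HEM=)`.
#' @export
count_lesion_masks <- function(masks, min_area = 0) {
  vapply(lesion_classes(), function(cl)
    as.integer(count_lesions(masks[[cl]], min_area = min_area)),
    integer(1))
}

#' Pixelwise segmentation metrics
#'
#' Confusion counts are accumulated over all pixels and the standard
#' derived metrics reported:
#' accuracy = (TP+TN)/(TP+FP+FN+TN), recall = TP/(TP+FN),
#' precision = TP/(TP+FP), F1 = 2PR/(P+R), and IoU = |A ∩ A'| / |A ∪ A'|.
#' Zero denominators yield `NA` (an explicit undefined marker), never a
#' silent 0.
#'
#' @param pred,truth 0/1 matrices of equal dimensions (prediction and
#'   ground truth).
#' @return List with `recall`, `precision`, `f1`, `accuracy`, `iou` and the
#'   raw `confusion` counts `c(TP=, FP=, FN=, TN=)`.
#' @export
seg_metrics <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth must have equal dimensions")
  cc <- confusion_counts(pred == 1L, truth == 1L)
  metrics_from_confusion(cc)
}

#' Confusion counts and their derived metrics
#'
#' @param pred_pos,truth_pos Logical vectors/matrices of equal length.
#' @return `confusion_counts`: named vector `c(TP=, FP=, FN=, TN=)`.
#' @export
confusion_counts <- function(pred_pos, truth_pos) {
  c(TP = sum(pred_pos & truth_pos),
    FP = sum(pred_pos & !truth_pos),
    FN = sum(!pred_pos & truth_pos),
    TN = sum(!pred_pos & !truth_pos))
}

#' @rdname confusion_counts
#' @param cc Named confusion vector `c(TP=, FP=, FN=, TN=)`.
#' @export
metrics_from_confusion <- function(cc) {
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  tp <- cc[["TP"]]; fp <- cc[["FP"]]; fn <- cc[["FN"]]; tn <- cc[["TN"]]
  recall <- sdiv(tp, tp + fn)
  precision <- sdiv(tp, tp + fp)
  f1 <- if (is.na(recall) || is.na(precision) || precision + recall == 0)
    NA_real_
  else 2 * precision * recall / (precision + recall)
  list(recall = recall, precision = precision, f1 = f1,
       accuracy = sdiv(tp + tn, tp + fp + fn + tn),
       iou = sdiv(tp, tp + fp + fn),
       confusion = cc)
}

#' Extract the three clinical lesion-count features from an image
#'
#' Runs the full per-class chain: contrast enhancement, patch-based
#' segmentation with the class's U-Net model, probability-map
#' reconstruction, 0.5 binarization, and contour counting.
#'
#' @param img A [fundus_image()] or `H x W x 3` array.
#' @param models Named list of trained segmentation models (`MA`, `EX`,
#'   `HEM`), see [train_seg_cv()].
#' @param min_area Passed to [count_lesions()].
#' @return Named integer vector `c(MA=, EX=, HEM=)`.
#' @export
extract_lesion_features <- function(img, models, min_area = 0) {
  miss <- setdiff(lesion_classes(), names(models))
  if (length(miss) > 0)
    stop("missing segmentation model for class: ", paste(miss, collapse = ", "))
  enh <- enhance(img)
  vapply(lesion_classes(), function(cl) {
    map <- predict_image(models[[cl]], enh)
    as.integer(count_lesions(binarize_map(map), min_area = min_area))
  }, integer(1))
}
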