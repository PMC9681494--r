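#' Zero the non-eye background of a fundus photograph
#'
#' Detects the circular eye region and sets every pixel outside it to zero
#' in all channels, leaving pixels inside the disc untouched. Detection is
#' parameter-free: Otsu threshold on the grayscale image, keep the largest
#' connected component, then a 5x5 morphological closing of the disc mask.
#'
#' @param img A [fundus_image()] or an `H x W x 3` array in \eqn{[0,1]}.
#' @return Same type as the input, with margins zeroed. The detected disc is
#'   attached as `attr(, "disc")` (logical matrix).
#' @export
zero_background <- function(img) {
  x <- if (inherits(img, "fundus_image")) img$data else img
  gray <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
  th <- tryCatch(EBImage::otsu(EBImage::Image(gray)), error = function(e) NA)
  fg <- if (is.na(th)) matrix(FALSE, nrow(gray), ncol(gray)) else gray > th
  if (!any(fg)) {
    warning("no above-threshold region found; image returned unchanged")
    return(img)
  }
  lab <- EBImage::bwlabel(fg)
  tab <- tabulate(lab[lab > 0])
  disc <- lab == which.max(tab)
  disc <- EBImage::closing(disc, EBImage::makeBrush(5, "disc")) > 0
  for (ch in 1:3) x[, , ch][!disc] <- 0
  out <- if (inherits(img, "fundus_image")) {
    img$data <- x; img
  } else x
  attr(out, "disc") <- disc
  out
}

#' Extract the green channel
#'
#' The green channel carries the highest contrast between retinal
#' structures in fundus photography, and is the single channel all later
#' enhancement and segmentation operate on.
#'
#' @param img A [fundus_image()] or `H x W x 3` array.
#' @return `H x W` numeric matrix (the G plane).
#' @export
green_channel <- function(img) {
  x <- if (inherits(img, "fundus_image")) img$data else img
  if (length(dim(x)) != 3 || dim(x)[3] != 3)
    stop("green_channel requires a 3-channel image")
  x[, , 2]
}

#' Contrast-limited adaptive histogram equalization
#'
#' CLAHE over an 8x8 tile grid (tile size fixed by the enhancement recipe;
#' the clip limit is the usual free parameter).
#'
#' @param x `H x W` matrix in \eqn{[0,1]}.
#' @param tile Tile grid, default `c(8, 8)`.
#' @param clip_limit Contrast clip limit (default 2).
#' @return `H x W` matrix in \eqn{[0,1]}, quantized to the 8-bit grid.
#' @export
clahe_enhance <- function(x, tile = c(8, 8), clip_limit = 2) {
  if (!is.matrix(x)) stop("clahe_enhance requires a single-channel matrix")
  if (nrow(x) < 2 * tile[1] || ncol(x) < 2 * tile[2])
    stop("image too small for the CLAHE tile grid")
  y <- EBImage::clahe(EBImage::Image(x), nx = tile[1], ny = tile[2],
                      limit = clip_limit)
  quantize8(as.matrix(EBImage::imageData(y)))
}

#' Gamma correction
#'
#' `out = 255 * (in/255)^gamma`, rounded to 8 bits — a monotone
#' non-decreasing map; `gamma < 1` brightens, endpoints 0 and 255 are fixed.
#'
#' @param x `H x W` matrix in \eqn{[0,1]}.
#' @param gamma Exponent, must be positive (default 0.8).
#' @return `H x W` matrix in \eqn{[0,1]} on the 8-bit grid.
#' @export
gamma_correct <- function(x, gamma = 0.8) {
  if (gamma <= 0) stop("gamma must be positive")
  quantize8(x^gamma)
}

#' Full contrast-enhancement chain
#'
#' Composition, in order: background zeroing, green-channel extraction,
#' CLAHE (8x8 tiles), gamma correction (gamma = 0.8). The eye-disc mask
#' found in the first step is re-applied at the end so the margins stay
#' exactly zero through the chain.
#'
#' @param img A [fundus_image()] or `H x W x 3` array.
#' @param clip_limit CLAHE clip limit.
#' @param gamma Gamma exponent.
#' @param tile CLAHE tile grid.
#' @return An `enhanced_image`: list with `data` (`H x W` matrix), `steps`
#'   (record of the applied operations and their parameters) and `disc`.
#' @export
enhance <- function(img, clip_limit = 2, gamma = 0.8, tile = c(8, 8)) {
  z <- zero_background(img)
  disc <- attr(z, "disc")
  g <- green_channel(z)
  e <- clahe_enhance(g, tile = tile, clip_limit = clip_limit)
  e <- gamma_correct(e, gamma = gamma)
  if (!is.null(disc)) e[!disc] <- 0
  structure(list(
    data = e,
    steps = list(
      list(op = "background_zeroed"),
      list(op = "green"),
      list(op = "clahe", tile = tile, clip_limit = clip_limit),
      list(op = "gamma", gamma = gamma)),
    disc = disc), class = "enhanced_image")
}

#' @export
print.enhanced_image <- function(x, ...) {
  cat(sprintf("enhanced_image %dx%d, steps: %s\n", nrow(x$data), ncol(x$data),
              paste(vapply(x$steps, `[[`, "", "op"), collapse = " -> ")))
  invisible(x)
}
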