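#' Specification for a synthetic fundus image
#'
#' Describes one synthetic color fundus photograph: a circular "eye" disc on
#' black margins, plus three classes of lesions drawn as blobs with
#' class-specific size, shape and color:
#' \describe{
#'   \item{MA}{microaneurysms — small dark-red dots;}
#'   \item{EX}{exudates — bright yellowish blobs;}
#'   \item{HEM}{hemorrhages — larger irregular dark blobs, each drawn as a
#'     union of 2–4 overlapping ellipses that still forms \emph{one} lesion
#'     (one connected mask component).}
#' }
#' Blob centers lie inside the eye disc and blobs are pairwise disjoint with
#' a minimum inter-blob gap of 2 px, so that contour-based counting of the
#' emitted masks is unambiguous and exactly recoverable.
#'
#' @param height,width Image dimensions in pixels.
#' @param eye_radius_fraction Eye-disc radius as a fraction of
#'   `min(height, width) / 2`, in (0, 1].
#' @param lesion_counts Named integer vector `c(MA=, EX=, HEM=)` of requested
#'   lesions per class (non-negative).
#' @param blob_radius_range Named list of length-2 numeric vectors giving the
#'   per-class radius range in pixels.
#' @param background_noise_sd Gaussian pixel noise, in 8-bit gray levels.
#' @param seed Integer RNG seed; identical spec + seed reproduces the image
#'   bit for bit.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(height = 256, width = 256,
                       eye_radius_fraction = 0.92,
                       lesion_counts = c(MA = 0L, EX = 0L, HEM = 0L),
                       blob_radius_range = list(MA = c(2, 4),
                                                EX = c(5, 9),
                                                HEM = c(7, 12)),
                       background_noise_sd = 2,
                       seed = 1L) {
  counts <- c(MA = 0L, EX = 0L, HEM = 0L)
  counts[names(lesion_counts)] <- as.integer(lesion_counts)
  if (any(counts < 0)) stop("lesion_counts must be non-negative")
  if (eye_radius_fraction <= 0 || eye_radius_fraction > 1)
    stop("eye_radius_fraction must be in (0, 1]")
  max_d <- 2 * max(vapply(blob_radius_range, max, numeric(1)))
  if (min(height, width) < 2 * max_d)
    stop("image dimensions must be at least twice the largest blob diameter")
  structure(list(height = as.integer(height), width = as.integer(width),
                 eye_radius_fraction = eye_radius_fraction,
                 lesion_counts = counts,
                 blob_radius_range = blob_radius_range,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("synth_spec: %dx%d, eye %.2f, MA=%d EX=%d HEM=%d, seed %d\n",
              x$height, x$width, x$eye_radius_fraction,
              x$lesion_counts["MA"], x$lesion_counts["EX"],
              x$lesion_counts["HEM"], x$seed))
  invisible(x)
}

# class -> RGB color of lesion pixels (values in [0,1])
.lesion_colors <- list(MA  = c(0.45, 0.10, 0.06),
                       EX  = c(0.98, 0.92, 0.45),
                       HEM = c(0.28, 0.06, 0.04))
.fundus_base <- c(0.80, 0.45, 0.20)

#' The three lesion classes, in canonical feature order
#'
#' @return `c("MA", "EX", "HEM")` — microaneurysms, exudates, hemorrhages.
#' @export
lesion_classes <- function() c("MA", "EX", "HEM")

#' A fundus image object
#'
#' Thin container around an `H x W x 3` numeric array with values in
#' \eqn{[0, 1]} (8-bit semantics: values lie on the grid k/255), keeping
#' source provenance and an optional severity grade 0–4.
#'
#' @param data `H x W x 3` numeric array in \eqn{[0,1]}.
#' @param path Source path, or `NA` for in-memory images.
#' @param severity Optional DR severity grade 0–4.
#' @return An object of class `fundus_image`.
#' @export
fundus_image <- function(data, path = NA_character_, severity = NA_integer_) {
  if (length(dim(data)) != 3 || dim(data)[3] != 3)
    stop("fundus image must be an H x W x 3 array")
  if (min(data) < 0 || max(data) > 1) stop("values must be in [0, 1]")
  structure(list(data = data, path = path,
                 severity = severity), class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("fundus_image %dx%d, severity %s, source %s\n", d[1], d[2],
              x$severity, x$path))
  invisible(x)
}

# Rasterize a (rotated) filled ellipse; returns an H x W logical matrix.
rasterize_ellipse <- function(H, W, ci, cj, a, b, theta) {
  pad <- ceiling(max(a, b)) + 1
  i0 <- max(1, floor(ci - pad)); i1 <- min(H, ceiling(ci + pad))
  j0 <- max(1, floor(cj - pad)); j1 <- min(W, ceiling(cj + pad))
  out <- matrix(FALSE, H, W)
  if (i0 > i1 || j0 > j1) return(out)
  ii <- i0:i1; jj <- j0:j1
  di <- outer(ii - ci, rep(1, length(jj)))
  dj <- outer(rep(1, length(ii)), jj - cj)
  u <- (di * cos(theta) + dj * sin(theta)) / a
  v <- (-di * sin(theta) + dj * cos(theta)) / b
  out[ii, jj] <- (u * u + v * v) <= 1
  out
}

# 2-px dilation (5x5 box) used to enforce the minimum inter-blob gap.
.dilate2 <- function(mask) {
  EBImage::dilate(mask, EBImage::makeBrush(5, "box")) > 0
}

# Sample one blob of `class` subject to: fully inside the eye disc, and no
# overlap with `forbidden` (existing blobs dilated by the gap). Bounded
# rejection sampling; NULL on failure.
.place_blob <- function(class, spec, cx, cy, R, forbidden, max_tries = 200) {
  H <- spec$height; W <- spec$width
  rng <- spec$blob_radius_range[[class]]
  for (t in seq_len(max_tries)) {
    r <- runif(1, rng[1], rng[2])
    # largest extent of the blob, used to keep it inside the disc
    ext <- if (class == "HEM") 1.9 * r else r
    rr <- runif(1, 0, max(R - ext - 2, 1))
    ang <- runif(1, 0, 2 * pi)
    ci <- cy + rr * sin(ang); cj <- cx + rr * cos(ang)
    blob <- switch(class,
      MA = rasterize_ellipse(H, W, ci, cj, r, r, 0),
      EX = rasterize_ellipse(H, W, ci, cj, r, r * runif(1, 0.7, 1),
                             runif(1, 0, pi)),
      HEM = {
        k <- sample(2:4, 1)
        m <- rasterize_ellipse(H, W, ci, cj, r, r * runif(1, 0.6, 1),
                               runif(1, 0, pi))
        pi0 <- ci; pj0 <- cj
        for (s in seq_len(k - 1)) {
          # center of the next ellipse stays inside the previous one so the
          # union is a single connected lesion
          off <- 0.5 * r
          pi0 <- pi0 + runif(1, -off, off)
          pj0 <- pj0 + runif(1, -off, off)
          m <- m | rasterize_ellipse(H, W, pi0, pj0,
                                     r * runif(1, 0.6, 0.9),
                                     r * runif(1, 0.45, 0.7),
                                     runif(1, 0, pi))
        }
        m
      })
    if (!any(blob)) next
    # inside-disc check on actual pixels
    idx <- which(blob, arr.ind = TRUE)
    if (any((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2 > (R - 1)^2)) next
    if (any(blob & forbidden)) next
    return(blob)
  }
  NULL
}

#' Generate one synthetic fundus image with ground-truth masks
#'
#' Draws the eye disc, samples the requested number of blobs per lesion
#' class by rejection sampling (pairwise disjoint, minimum 2 px gap, centers
#' inside the disc), and renders both the RGB image and one binary mask per
#' class. Healthy images (all counts zero) get all-black masks.
#'
#' @param spec A [synth_spec()].
#' @return A list with elements `image` (a [fundus_image()]), `masks` (named
#'   list of `H x W` 0/1 integer matrices for MA, EX, HEM), `label`
#'   (`"DR"` if any lesion was requested, else `"healthy"`), and `disc`
#'   (logical eye-disc mask, useful as a preprocessing oracle).
#' @export
generate_fundus_image <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    H <- spec$height; W <- spec$width
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    R <- spec$eye_radius_fraction * min(H, W) / 2
    di <- outer(seq_len(H) - cy, rep(1, W))
    dj <- outer(rep(1, H), seq_len(W) - cx)
    disc <- (di * di + dj * dj) <= R * R
    rad2 <- (di * di + dj * dj) / (R * R)

    masks <- lapply(lesion_classes(), function(cl) matrix(0L, H, W))
    names(masks) <- lesion_classes()
    forbidden <- !disc  # blobs must keep off the margins entirely
    for (cl in lesion_classes()) {
      n <- spec$lesion_counts[[cl]]
      for (b in seq_len(n)) {
        blob <- .place_blob(cl, spec, cx, cy, R, forbidden)
        if (is.null(blob))
          stop(sprintf(
            "infeasible packing: could not place %s blob %d of %d", cl, b, n))
        masks[[cl]][blob] <- 1L
        forbidden <- forbidden | .dilate2(blob)
      }
    }

    # render: shaded fundus disc, then lesions, then noise, then 8-bit grid
    img <- array(0, dim = c(H, W, 3))
    shade <- 1 - 0.35 * rad2
    for (ch in 1:3) {
      plane <- .fundus_base[ch] * shade
      for (cl in lesion_classes())
        plane[masks[[cl]] == 1L] <- .lesion_colors[[cl]][ch]
      plane <- plane + rnorm(H * W, 0, spec$background_noise_sd / 255)
      plane[!disc] <- 0
      img[, , ch] <- plane
    }
    img <- quantize8(img)

    total <- sum(vapply(masks, sum, numeric(1)))
    list(image = fundus_image(img,
                              severity = if (total > 0) NA_integer_ else 0L),
         masks = masks,
         label = if (total > 0) "DR" else "healthy",
         disc = disc)
  })
}

.severity_from_total <- function(total) {
  if (total == 0) return(0L)
  as.integer(cut(total, breaks = c(0, 2, 5, 8, Inf), labels = FALSE))
}

#' Generate a synthetic dataset with a manifest
#'
#' Writes `n_healthy + n_dr` synthetic fundus images and their three
#' per-lesion masks as PNG files, together with a manifest CSV with header
#' `image,ma_mask,ex_mask,hem_mask,label,severity`. Healthy rows reference
#' all-black masks (identical dimensions to the image), mirroring how
#' lesion-free ground truth is represented in public DR datasets. For DR
#' rows, per-class lesion counts are drawn uniformly between 0 and the
#' template's `lesion_counts`, re-drawn until at least one lesion is
#' present; the severity grade 0–4 increases with the total lesion count.
#'
#' @param n_healthy,n_dr Number of healthy / DR images (non-negative).
#' @param template A [synth_spec()] whose `lesion_counts` act as per-class
#'   maxima for DR images.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed controlling the whole dataset.
#' @return The manifest as a data.frame (paths relative to `dir`; the
#'   directory is recorded in `attr(, "dir")`), invisibly also written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
generate_fundus_dataset <- function(n_healthy, n_dr, template = synth_spec(),
                                    dir, seed = 1L) {
  stopifnot(n_healthy >= 0, n_dr >= 0)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  n <- n_healthy + n_dr
  labels <- rep(c("healthy", "DR"), c(n_healthy, n_dr))
  rows <- vector("list", n)
  with_seed(seed, {
    img_seeds <- sample.int(.Machine$integer.max, n)
    for (i in seq_len(n)) {
      if (labels[i] == "healthy") {
        counts <- c(MA = 0L, EX = 0L, HEM = 0L)
      } else {
        mx <- template$lesion_counts
        repeat {
          counts <- vapply(lesion_classes(), function(cl)
            sample.int(mx[[cl]] + 1L, 1L) - 1L, integer(1))
          if (sum(counts) > 0) break
        }
      }
      sp <- template
      sp$lesion_counts <- counts
      sp$seed <- img_seeds[i]
      gen <- generate_fundus_image(sp)
      stem <- sprintf("img_%04d", i)
      ipath <- paste0(stem, ".png")
      mpaths <- paste0(stem, "_", tolower(lesion_classes()), "_mask.png")
      write_image(gen$image$data, file.path(dir, ipath))
      for (k in seq_along(lesion_classes()))
        write_mask(gen$masks[[k]], file.path(dir, mpaths[k]))
      rows[[i]] <- data.frame(image = ipath, ma_mask = mpaths[1],
                              ex_mask = mpaths[2], hem_mask = mpaths[3],
                              label = gen$label,
                              severity = .severity_from_total(
                                sum(vapply(gen$masks, sum, numeric(1)))),
                              stringsAsFactors = FALSE)
    }
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "dir") <- dir
  manifest
}

#' Read and validate a dataset manifest
#'
#' @param path Path to a manifest CSV with columns
#'   `image,ma_mask,ex_mask,hem_mask,label,severity`.
#' @param check Validate that every referenced file exists, that labels are
#'   `healthy`/`DR`, and that `label == "healthy"` iff `severity == 0`
#'   where severity is given.
#' @return Manifest data.frame with `attr(, "dir")` set to its directory.
#' @export
read_manifest <- function(path, check = TRUE) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "ma_mask", "ex_mask", "hem_mask", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  dir <- dirname(normalizePath(path))
  if (check) {
    files <- unlist(m[, c("image", "ma_mask", "ex_mask", "hem_mask")])
    missing <- files[!file.exists(file.path(dir, files))]
    if (length(missing) > 0)
      stop("manifest references missing files: ",
           paste(head(missing, 3), collapse = ", "))
    if (!all(m$label %in% c("healthy", "DR")))
      stop("labels must be 'healthy' or 'DR'")
    if ("severity" %in% names(m)) {
      sv <- !is.na(m$severity)
      if (any((m$label[sv] == "healthy") != (m$severity[sv] == 0)))
        stop("label 'healthy' must coincide with severity 0")
    }
  }
  attr(m, "dir") <- dir
  m
}

#' Image and mask PNG input/output
#'
#' Images are exchanged as 8-bit PNG; masks as single-channel 8-bit PNG with
#' foreground 255. Arrays are `H x W (x 3)` with values in \eqn{[0,1]}
#' internally; masks are 0/1 integer matrices.
#'
#' @param x `H x W x 3` array in \eqn{[0,1]} (`write_image`) or 0/1 matrix
#'   (`write_mask`).
#' @param path File path; format follows the extension (.png/.jpg/.tiff).
#' @return `read_image`: an `H x W x 3` array; `read_mask`: a 0/1 integer
#'   matrix; writers return `path` invisibly.
#' @export
write_image <- function(x, path) {
  EBImage::writeImage(EBImage::Image(aperm(x, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' @rdname write_image
#' @export
write_mask <- function(x, path) {
  EBImage::writeImage(EBImage::Image(t(x * 1.0)), path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2) {
    a <- array(t(as.array(img)), dim = c(d[2], d[1], 3))  # gray -> replicate
    a[, , 2] <- a[, , 1]; a[, , 3] <- a[, , 1]
    return(a)
  }
  a <- aperm(as.array(img), c(2, 1, 3))
  a[, , 1:3, drop = FALSE][, , 1:3]
}

#' @rdname write_image
#' @export
read_mask <- function(path) {
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) == 3) a <- a[, , 1]
  m <- t(a)
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}
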