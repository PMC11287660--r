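#' Grayscale image container
#'
#' A 2D intensity raster (rows = image rows) with an 8- or 16-bit depth.
#' Intensities live on the integer scale `[0, 2^bit_depth - 1]` but are
#' stored as doubles so histogram-matched images keep sub-level precision.
#'
#' @param pixels numeric matrix of intensities.
#' @param bit_depth 8 or 16.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, bit_depth = 8L) {
  pixels <- as.matrix(pixels)
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (!all(is.finite(pixels))) stop("non-finite pixel value")
  if (min(pixels) < 0 || max(pixels) > 2^bit_depth - 1) {
    stop("pixel values outside [0, ", 2^bit_depth - 1, "]")
  }
  structure(list(pixels = pixels, bit_depth = bit_depth),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d-bit, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a grayscale image from TIFF or PNG
#'
#' RGB input is converted to luminance with the Rec. 709 weights
#' (0.2126, 0.7152, 0.0722); an alpha channel is ignored.
#'
#' @param path a `.tif`/`.tiff` or `.png` file.
#' @return A [gray_image()].
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    depth <- if (max(img) > 255) 16L else 8L
  } else if (ext == "png") {
    img <- png::readPNG(path)
    depth <- 8L
    if (max(img) <= 1) {           # readPNG scales to [0,1]
      img <- img * 255
    }
  } else {
    stop("unsupported image format: .", ext)
  }
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3L]
    w <- c(0.2126, 0.7152, 0.0722)
    img <- if (nch >= 3L) {
      img[, , 1L] * w[1L] + img[, , 2L] * w[2L] + img[, , 3L] * w[3L]
    } else {
      img[, , 1L]
    }
  }
  gray_image(round(img), depth)
}

#' Write a grayscale image
#'
#' Integer images go to 8/16-bit TIFF or PNG; continuous-valued maps (e.g.
#' relative-difference maps) go to 32-bit float TIFF with
#' `float = TRUE`.
#'
#' @param image a [gray_image()] or numeric matrix (when `float = TRUE`).
#' @param path output path (`.tif`/`.tiff`/`.png`).
#' @param float write a 32-bit float TIFF of raw values (NA stored as 0).
#' @return `path`, invisibly.
#' @export
write_gray <- function(image, path, float = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (float) {
    m <- if (inherits(image, "gray_image")) image$pixels else as.matrix(image)
    m[!is.finite(m)] <- 0
    tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = FALSE)
    return(invisible(path))
  }
  stopifnot(inherits(image, "gray_image"))
  scaled <- image$pixels / (2^image$bit_depth - 1)
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = image$bit_depth)
  } else if (ext == "png") {
    png::writePNG(scaled, path)
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}

#' Specimen foreground mask by edge detection
#'
#' Reproducible chain standing in for "outline the edge automatically":
#' Sobel gradient magnitude, Otsu threshold on the gradient map,
#' morphological closing (disc brush), hole filling, then retention of
#' connected components covering at least `min_object_fraction` of the
#' image. Because edge positions are invariant under monotone brightness
#' maps, the mask of an image and of its gamma-transformed copy agree up to
#' threshold effects.
#'
#' @param image a [gray_image()].
#' @param min_object_fraction minimum component area as a fraction of the
#'   image (drops specks and background texture).
#' @param brush_size diameter of the closing brush in pixels (odd).
#' @return A logical matrix, `TRUE` on the specimen.
#' @export
edge_mask <- function(image, min_object_fraction = 0.01, brush_size = 5L) {
  stopifnot(inherits(image, "gray_image"))
  px <- image$pixels / (2^image$bit_depth - 1)
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L, byrow = TRUE)
  gx <- EBImage::filter2(px, sx)
  gy <- EBImage::filter2(px, t(sx))
  grad <- sqrt(gx^2 + gy^2)
  if (max(grad) <= .Machine$double.eps) {
    stop("no edges detected (constant image)")
  }
  gradn <- grad / max(grad)
  thr <- EBImage::otsu(EBImage::Image(gradn), range = c(0, 1))
  edges <- gradn > thr
  closed <- EBImage::closing(edges, EBImage::makeBrush(brush_size, "disc"))
  filled <- EBImage::fillHull(closed)
  lab <- EBImage::bwlabel(filled)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_object_fraction * length(px)])
  if (length(keep) == 0L) {
    stop("no connected component covers >= ", min_object_fraction,
         " of the image; lower min_object_fraction")
  }
  matrix(lab %in% keep, nrow(px), ncol(px))
}

#' Histogram matching restricted to a mask
#'
#' Classic CDF quantile mapping: each in-mask source intensity v is sent to
#' the reference quantile at the source's mid-rank CDF of v (the mid-rank
#' convention `(F(v-) + F(v))/2` makes a constant source map to the
#' reference median). Only in-mask pixels define the two CDFs and only
#' in-mask pixels are remapped; the rest pass through unchanged. The mapping
#' is monotone, idempotent, and inverts any monotone brightness distortion
#' up to quantization.
#'
#' @param source a [gray_image()] to be remapped (e.g. the model render).
#' @param reference a [gray_image()] supplying the target histogram (e.g.
#'   the SEM micrograph).
#' @param mask logical matrix; `TRUE` pixels participate.
#' @return A [gray_image()] with the same dimensions and bit depth as
#'   `source`.
#' @export
histogram_match <- function(source, reference, mask) {
  stopifnot(inherits(source, "gray_image"), inherits(reference, "gray_image"))
  if (!all(dim(source$pixels) == dim(reference$pixels)) ||
      !all(dim(source$pixels) == dim(mask))) {
    stop("source, reference and mask must share dimensions")
  }
  if (!any(mask)) stop("mask is empty")
  src <- source$pixels[mask]
  ref <- reference$pixels[mask]
  mid_cdf <- function(v) {
    tab <- sort(unique(v))
    cnt <- tabulate(match(v, tab))
    cum <- cumsum(cnt)
    list(values = tab, p = (cum - cnt / 2) / length(v))
  }
  s <- mid_cdf(src)
  r <- mid_cdf(ref)
  mapped_u <- if (length(r$values) == 1L) {
    rep(r$values, length(s$values))
  } else {
    stats::approx(r$p, r$values, xout = s$p, rule = 2)$y
  }
  out <- source$pixels
  out[mask] <- mapped_u[match(src, s$values)]
  gray_image(pmin(pmax(out, 0), 2^source$bit_depth - 1), source$bit_depth)
}

#' Per-pixel relative difference between a model render and an SEM image
#'
#' For each in-mask pixel i the relative difference is
#' \eqn{|X_i^M - X_i^S| / X_i^S}, normalising by the SEM intensity — the
#' comparison is deliberately asymmetric in its arguments. Pixels where the
#' SEM intensity is zero have an undefined ratio; they are excluded from the
#' map and the summaries, and counted in `excluded_zero_pixels` rather than
#' regularised with an arbitrary epsilon.
#'
#' @param model_img model-render [gray_image()] (numerator side), normally
#'   already histogram-matched to `sem_img`.
#' @param sem_img SEM [gray_image()] (denominator side).
#' @param mask logical matrix of specimen pixels.
#' @return A `comparison_result`: list with `mask`, `reldiff` (matrix, `NA`
#'   outside the mask and at zero denominators), `mean_reldiff`,
#'   `median_reldiff`, `n_defined`, `excluded_zero_pixels`.
#' @export
relative_difference <- function(model_img, sem_img, mask) {
  stopifnot(inherits(model_img, "gray_image"), inherits(sem_img, "gray_image"))
  if (!all(dim(model_img$pixels) == dim(sem_img$pixels)) ||
      !all(dim(model_img$pixels) == dim(mask))) {
    stop("images and mask must share dimensions")
  }
  s <- sem_img$pixels
  m <- model_img$pixels
  defined <- mask & s > 0
  if (!any(defined)) stop("all in-mask SEM denominators are zero")
  rd <- matrix(NA_real_, nrow(s), ncol(s))
  rd[defined] <- abs(m[defined] - s[defined]) / s[defined]
  vals <- rd[defined]
  structure(
    list(mask = mask, reldiff = rd,
         mean_reldiff = mean(vals), median_reldiff = stats::median(vals),
         n_defined = sum(defined),
         excluded_zero_pixels = sum(mask & s == 0)),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(paste0("<comparison_result> %d in-mask pixels ",
                     "(%d zero-denominator excluded)\n",
                     "  mean relative difference:   %.4f\n",
                     "  median relative difference: %.4f\n"),
              x$n_defined, x$excluded_zero_pixels,
              x$mean_reldiff, x$median_reldiff))
  invisible(x)
}

#' Full model-vs-SEM comparison pipeline
#'
#' Composition of the validation chain for a pre-aligned image pair (the
#' render captured at the same view angle and scale as the micrograph):
#' specimen mask from the SEM image by [edge_mask()], photometric alignment
#' of the render by in-mask [histogram_match()], then the per-pixel
#' [relative_difference()] map and its summaries. Deterministic: identical
#' inputs give bit-identical results.
#'
#' @param model_img model-render [gray_image()].
#' @param sem_img SEM [gray_image()].
#' @param min_object_fraction passed to [edge_mask()].
#' @return A `comparison_result` (see [relative_difference()]) with the
#'   matched render attached as `matched_model`.
#' @examples
#' pair <- make_image_pair(96, 72, transform = "gamma", gamma = 0.5)
#' res <- compare_pair(pair$distorted, pair$reference)
#' res$mean_reldiff
#' @export
compare_pair <- function(model_img, sem_img, min_object_fraction = 0.01) {
  mask <- edge_mask(sem_img, min_object_fraction = min_object_fraction)
  matched <- histogram_match(model_img, sem_img, mask)
  res <- relative_difference(matched, sem_img, mask)
  res$matched_model <- matched
  res
}
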