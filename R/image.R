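# Pixel-grid primitives: grayscale conversion, integral images,
# constant-time rectangle sums, histograms, PNG/TIFF I/O.
#
# Convention used throughout the package: an image is a plain numeric
# matrix of intensities in [0, 1], indexed [row, col] = [y + 1, x + 1]
# with x = column and y = row, both 0-based in the user-facing API.
# Rectangles are half-open: [x, x + w) x [y, y + h).

#' Validate an image matrix
#'
#' @param img Numeric matrix of finite intensities; `ncol` is the image
#'   width (x), `nrow` the height (y).
#' @return `img`, invisibly.
#' @keywords internal
validate_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort("An image must be a numeric matrix.")
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    abort("An image must have width >= 1 and height >= 1.")
  }
  if (!all(is.finite(img))) {
    abort("All image intensities must be finite.")
  }
  invisible(img)
}

#' Convert an image to unit-range grayscale
#'
#' Single-channel input is rescaled by its bit-depth maximum; 3-channel
#' (RGB) input is combined with the ITU-R BT.601 luma weights
#' (0.299, 0.587, 0.114) after per-channel rescaling.
#'
#' @param image A numeric matrix (1 channel) or an `h x w x c` array with
#'   `c` of 1 or 3. Samples may be integers on an 8- or 16-bit scale or
#'   floats already in `[0, 1]`.
#' @param bit_depth Maximum-value bit depth of integer samples (8 or 16).
#'   When `NULL`, inferred: values within `[0, 1]` are taken as already
#'   normalized, values up to 255 as 8-bit, larger as 16-bit.
#' @return A numeric matrix with intensities in `[0, 1]`.
#' @examples
#' to_grayscale(matrix(255, 2, 2))           # all 1
#' to_grayscale(array(c(255, 0, 0), c(1, 1, 3)))  # 0.299
#' @export
to_grayscale <- function(image, bit_depth = NULL) {
  if (is.matrix(image)) {
    chans <- list(image)
  } else if (is.array(image) && length(dim(image)) == 3L) {
    nc <- dim(image)[3]
    if (!nc %in% c(1L, 3L)) {
      abort(sprintf("Unsupported channel count: %d (expected 1 or 3).", nc))
    }
    chans <- lapply(seq_len(nc), function(k)
      matrix(image[, , k], dim(image)[1], dim(image)[2]))
  } else {
    abort("`image` must be a matrix or a 3-d array.")
  }
  if (!all(vapply(chans, function(m) all(is.finite(m)), logical(1)))) {
    abort("All image samples must be finite.")
  }
  vmax <- max(vapply(chans, max, numeric(1)), 0)
  scale <- if (!is.null(bit_depth)) {
    2^bit_depth - 1
  } else if (vmax <= 1) 1 else if (vmax <= 255) 255 else 65535
  chans <- lapply(chans, function(m) m / scale)
  out <- if (length(chans) == 1L) {
    chans[[1]]
  } else {
    0.299 * chans[[1]] + 0.587 * chans[[2]] + 0.114 * chans[[3]]
  }
  validate_image(out)
  out
}

#' Rectangle constructor
#'
#' Rectangles use 0-based, half-open pixel coordinates:
#' `[x, x + w) x [y, y + h)`.
#'
#' @param x,y Top-left corner (0-based; may be negative — rectangles may
#'   extend beyond the image, the out-of-image area contributes nothing
#'   to sums).
#' @param w,h Width and height in pixels, both `>= 1`.
#' @return A tibble with columns `x`, `y`, `w`, `h` (vectorized).
#' @export
rect <- function(x, y, w, h) {
  if (any(w < 1) || any(h < 1)) abort("Rectangles need w >= 1 and h >= 1.")
  tibble(x = as.numeric(x), y = as.numeric(y),
         w = as.numeric(w), h = as.numeric(h))
}

#' Integral image (summed-area table)
#'
#' Entry `(x, y)` holds the inclusive cumulative sum of the source over
#' `[0, x] x [0, y]`, enabling constant-time rectangle sums by the
#' four-corner inclusion–exclusion rule (Viola–Jones).
#'
#' @param img An image matrix (see [validate_image()]).
#' @return An object of class `integral_image` with fields `sums`
#'   (the cumulative-sum matrix), `width`, `height`.
#' @examples
#' ii <- integral_image(matrix(c(1, 3, 2, 4), 2, 2))
#' ii$sums
#' @export
integral_image <- function(img) {
  validate_image(img)
  s <- apply(img, 2, cumsum)
  if (nrow(img) == 1L) s <- matrix(s, nrow = 1L)
  s <- t(apply(s, 1, cumsum))
  if (ncol(img) == 1L) s <- matrix(s, ncol = 1L)
  h <- nrow(img); w <- ncol(img)
  # zero-padded copy: one extra leading row/col so clamped lookups are a
  # single pmin/pmax + gather
  pad <- matrix(0, h + 1L, w + 1L)
  pad[-1L, -1L] <- s
  structure(list(sums = s, width = w, height = h, .pad = pad),
            class = "integral_image")
}

#' @export
print.integral_image <- function(x, ...) {
  cat(sprintf("<integral_image %dx%d, total = %g>\n",
              x$width, x$height, x$sums[x$height, x$width]))
  invisible(x)
}

# Clamped lookup of the inclusive cumulative sum at 0-based (xi, yi):
# negative indices give 0, indices past the far edge clamp to it.
# All arguments vectorized.
.ii_lookup <- function(ii, xi, yi) {
  r <- pmax(pmin(yi, ii$height - 1), -1) + 2
  c <- pmax(pmin(xi, ii$width - 1), -1) + 2
  ii$.pad[(c - 1) * (ii$height + 1L) + r]   # flat column-major index
}

# Vectorized core of box_sum (0-based x, y; half-open w, h).
.box_sum <- function(ii, x, y, w, h) {
  .ii_lookup(ii, x + w - 1, y + h - 1) -
    .ii_lookup(ii, x - 1, y + h - 1) -
    .ii_lookup(ii, x + w - 1, y - 1) +
    .ii_lookup(ii, x - 1, y - 1)
}

#' Rectangle sum from an integral image
#'
#' Sums source pixels over `r` intersected with the image bounds; parts
#' of `r` outside the image contribute 0. Constant time per rectangle.
#'
#' @param ii An [integral_image()].
#' @param r A rectangle as produced by [rect()] (a data frame with
#'   columns `x`, `y`, `w`, `h`; may have several rows).
#' @return Numeric vector of sums, one per row of `r`.
#' @export
box_sum <- function(ii, r) {
  stopifnot(inherits(ii, "integral_image"))
  if (!is.data.frame(r) || !all(c("x", "y", "w", "h") %in% names(r))) {
    abort("`r` must be a data frame with columns x, y, w, h (see rect()).")
  }
  .box_sum(ii, r$x, r$y, r$w, r$h)
}

#' 256-bin intensity histogram
#'
#' Quantizes unit-range intensities to 8-bit levels
#' `floor(intensity * 255)` (clipped to 0..255) and counts pixels per
#' level, mirroring the histogram of the written 8-bit image.
#'
#' @param img An image matrix.
#' @return Integer vector of 256 counts (levels 0..255); the counts sum
#'   to `width * height`.
#' @export
histogram256 <- function(img) {
  validate_image(img)
  lev <- pmax(pmin(floor(img * 255), 255), 0)
  tabulate(as.integer(lev) + 1L, nbins = 256L)
}

#' Read an image file as unit-range grayscale
#'
#' PNG and TIFF (8/16-bit, single- or multi-page) are supported; RGB
#' pages are converted with BT.601 luma weights.
#'
#' @param path File path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param all For TIFF: read all pages (returns a list of matrices).
#' @return An image matrix, or a list of them when `all = TRUE`.
#' @export
read_image <- function(path, all = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)  # readPNG already rescales to [0, 1]
    to_grayscale(drop_alpha(a))
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, all = all)
    if (all) lapply(a, function(p) to_grayscale(drop_alpha(p)))
    else to_grayscale(drop_alpha(a))
  } else {
    abort(sprintf("Unsupported image extension: '%s'.", ext))
  }
}

# readPNG/readTIFF may return an alpha channel; drop it.
drop_alpha <- function(a) {
  if (is.array(a) && length(dim(a)) == 3L && dim(a)[3] %in% c(2L, 4L)) {
    a <- a[, , seq_len(dim(a)[3] - 1L), drop = FALSE]
    if (dim(a)[3] == 1L) a <- a[, , 1L]
  }
  a
}

#' Write a grayscale image
#'
#' Intensities are clipped to `[0, 1]` and quantized; grayscale PNG is
#' written 8-bit (the package default), TIFF either 8- or 16-bit.
#'
#' @param img An image matrix.
#' @param path Output path (`.png`, `.tif`, `.tiff`).
#' @param bit_depth 8 (default) or 16; 16-bit output requires TIFF.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bit_depth = 8) {
  validate_image(img)
  img <- pmax(pmin(img, 1), 0)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bit_depth != 8) abort("PNG output is 8-bit; use TIFF for 16-bit.")
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!bit_depth %in% c(8, 16)) abort("`bit_depth` must be 8 or 16.")
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(bit_depth))
  } else {
    abort(sprintf("Unsupported image extension: '%s'.", ext))
  }
  invisible(path)
}
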