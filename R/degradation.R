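# Controlled image corruptions used by the robustness study:
# Gaussian blur (defocus emulation) and linear brightness/contrast
# adjustment.

#' Blur specification
#'
#' Integer blur levels map to Gaussian sigma by `sigma = 0.5 * level`
#' (the package's calibration of the otherwise unitless "blur level");
#' the kernel radius is `ceil(3 * sigma)`, so the kernel side is odd.
#' Level 0 is the identity.
#'
#' @param level Integer level `>= 0`.
#' @param sigma_per_level Sigma increment per level (default 0.5).
#' @return A list of class `blur_spec` with `level`, `sigma`, `radius`.
#' @export
blur_spec <- function(level, sigma_per_level = 0.5) {
  assert_scalar_number(level, "level", lower = 0)
  assert_scalar_number(sigma_per_level, "sigma_per_level")
  if (sigma_per_level <= 0) abort("`sigma_per_level` must be > 0.")
  sigma <- sigma_per_level * level
  structure(list(level = as.integer(level), sigma = sigma,
                 radius = if (sigma > 0) as.integer(ceiling(3 * sigma)) else 0L),
            class = "blur_spec")
}

#' Photometric (brightness/contrast) specification
#'
#' Linear per-pixel adjustment `g = gain * f + offset` on the unit
#' intensity scale, clipped to `[0, 1]`. For the brightness sweeps the
#' level-to-offset map is `offset = level / 255`, `gain = 1` (one 8-bit
#' gray level of additive brightness per level).
#'
#' @param gain Multiplicative constant, `> 0`.
#' @param offset Additive constant on the unit scale.
#' @param level Convenience alternative: integer brightness level,
#'   mapped via `offset = level * offset_per_level`, `gain = 1`.
#' @param offset_per_level Offset increment per level (default 1/255).
#' @return A list of class `photometric_spec`.
#' @export
photometric_spec <- function(gain = 1, offset = 0, level = NULL,
                             offset_per_level = 1 / 255) {
  if (!is.null(level)) {
    assert_scalar_number(level, "level", lower = 0)
    offset <- level * offset_per_level
    gain <- 1
  }
  assert_scalar_number(gain, "gain")
  if (gain <= 0) abort("`gain` must be > 0.")
  assert_scalar_number(offset, "offset")
  structure(list(gain = gain, offset = offset), class = "photometric_spec")
}

# Symmetric-reflection index vector for 1-d padding (edge included:
# c b a | a b c ... ).
.reflect_idx <- function(n, rad) {
  if (rad == 0L) return(seq_len(n))
  if (rad > n) {
    # fold repeatedly for kernels wider than the image
    base <- c(seq_len(n), rev(seq_len(n)))
    idx <- base[((seq(-rad, n - 1 + rad)) %% (2 * n)) + 1]
    return(idx)
  }
  c(rev(seq_len(rad)), seq_len(n), n:(n - rad + 1L))
}

#' Gaussian blur
#'
#' Separable convolution with a normalized Gaussian kernel
#' (`sigma = 0.5 * level`, radius `ceil(3 sigma)`), symmetric-reflected
#' borders.
#'
#' @param img An image matrix.
#' @param spec A [blur_spec()] (or a bare integer level).
#' @return The blurred image matrix.
#' @export
apply_blur <- function(img, spec) {
  validate_image(img)
  if (!inherits(spec, "blur_spec")) spec <- blur_spec(spec)
  if (spec$level == 0L || spec$sigma <= 0) return(img)
  rad <- spec$radius
  k <- exp(-(-rad:rad)^2 / (2 * spec$sigma^2))
  k <- k / sum(k)
  # rows (vertical pass)
  ri <- .reflect_idx(nrow(img), rad)
  pad <- img[ri, , drop = FALSE]
  out <- matrix(0, nrow(img), ncol(img))
  for (t in seq_along(k)) {
    out <- out + k[t] * pad[(t - 1L) + seq_len(nrow(img)), , drop = FALSE]
  }
  # columns (horizontal pass)
  ci <- .reflect_idx(ncol(img), rad)
  pad <- out[, ci, drop = FALSE]
  out <- matrix(0, nrow(img), ncol(img))
  for (t in seq_along(k)) {
    out <- out + k[t] * pad[, (t - 1L) + seq_len(ncol(img)), drop = FALSE]
  }
  out
}

#' Linear brightness/contrast adjustment
#'
#' Per-pixel `gain * f + offset`, clipped to `[0, 1]`. The fraction of
#' clipped pixels is attached as attribute `clip_fraction`.
#'
#' @param img An image matrix.
#' @param spec A [photometric_spec()].
#' @return The adjusted image matrix.
#' @export
apply_photometric <- function(img, spec) {
  validate_image(img)
  stopifnot(inherits(spec, "photometric_spec"))
  out <- spec$gain * img + spec$offset
  clipped <- out < 0 | out > 1
  out <- pmax(pmin(out, 1), 0)
  attr(out, "clip_fraction") <- mean(clipped)
  out
}

#' Power-law (true gamma) adjustment
#'
#' `g = f ^ gamma` on the unit scale. Provided for users who want a
#' literal gamma curve; the brightness sweeps use the linear
#' [apply_photometric()] adjustment.
#'
#' @param img An image matrix.
#' @param gamma Exponent, `> 0`.
#' @return The adjusted image matrix.
#' @export
apply_gamma <- function(img, gamma) {
  validate_image(img)
  assert_scalar_number(gamma, "gamma")
  if (gamma <= 0) abort("`gamma` must be > 0.")
  pmax(pmin(img, 1), 0)^gamma
}
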