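# 64-dimensional Haar-wavelet descriptors.
#
# An axis-aligned window of side 20s around the point is divided into
# 4x4 subregions; each subregion contributes the four sums
# (sum dx, sum dy, sum |dx|, sum |dy|) of Gaussian-weighted Haar-wavelet
# responses at 5x5 samples, giving 4*4*4 = 64 ordered components, then
# the vector is normalized to unit length. The upright (unrotated)
# variant is used: microscope stage motion is translational.

#' Descriptor parameters
#'
#' @param window_factor Sampling window side as a multiple of the point
#'   scale `s` (default 20).
#' @param haar_factor Haar wavelet side as a multiple of `s` (default 2).
#' @param sigma_factor Gaussian weighting sigma as a multiple of `s`
#'   (default 3.3).
#' @return A list of class `descriptor_params`.
#' @export
descriptor_params <- function(window_factor = 20, haar_factor = 2,
                              sigma_factor = 3.3) {
  assert_scalar_number(window_factor, "window_factor", lower = 1)
  assert_scalar_number(haar_factor, "haar_factor", lower = 0.1)
  assert_scalar_number(sigma_factor, "sigma_factor", lower = 0.1)
  structure(list(window_factor = window_factor, haar_factor = haar_factor,
                 sigma_factor = sigma_factor),
            class = "descriptor_params")
}

# Sample grid offsets in units of s: 20 positions per axis at
# (k + 0.5) * s for k = -10..9, i.e. 5 per subregion.
.desc_grid <- function() {
  k <- -10:9
  expand.grid(kx = k, ky = k)
}

#' Describe one interest point
#'
#' Haar responses use wavelets of side `2 * round(s)` evaluated through
#' the integral image at sample centres rounded half-up to the pixel
#' lattice; `dx` is right-lobe minus left-lobe, `dy` bottom minus top
#' (image y grows downward). Samples are weighted by a Gaussian of
#' sigma `3.3 s` centred on the point; samples whose centre rounds
#' outside the image are skipped.
#'
#' @param ii An [integral_image()] of the source image.
#' @param x,y Sub-pixel point location (0-based).
#' @param scale Point scale `s` (> 0).
#' @param sign Laplacian sign carried by the point (+/-1).
#' @param params A [descriptor_params()] object.
#' @return A list of class `descriptor`: `v` (64 components, unit norm
#'   or all zero for a flat patch), `sign`, `norm` (Euclidean length
#'   before normalization).
#' @export
describe_point <- function(ii, x, y, scale, sign = 1,
                           params = descriptor_params()) {
  stopifnot(inherits(ii, "integral_image"))
  if (!is.finite(scale) || scale <= 0) abort("`scale` must be positive.")
  s <- scale
  g <- .desc_grid()
  ux <- (g$kx + 0.5) * s * params$window_factor / 20
  uy <- (g$ky + 0.5) * s * params$window_factor / 20
  cx <- round_half_up(x + ux)
  cy <- round_half_up(y + uy)
  r <- max(1L, round_half_up(s * params$haar_factor / 2))
  keep <- cx >= 0 & cx < ii$width & cy >= 0 & cy < ii$height
  if (!any(keep)) {
    abort("The sampling window lies entirely outside the image.")
  }
  w <- exp(-(ux^2 + uy^2) / (2 * (params$sigma_factor * s)^2))
  dx <- .box_sum(ii, cx, cy - r, r, 2L * r) -
    .box_sum(ii, cx - r, cy - r, r, 2L * r)
  dy <- .box_sum(ii, cx - r, cy, 2L * r, r) -
    .box_sum(ii, cx - r, cy - r, 2L * r, r)
  dx <- ifelse(keep, w * dx, 0)
  dy <- ifelse(keep, w * dy, 0)
  sub <- 4L * ((g$ky + 10L) %/% 5L) + ((g$kx + 10L) %/% 5L)  # row-major 0..15
  v <- numeric(64)
  for (b in 0:15) {
    m <- sub == b
    v[4L * b + 1L] <- sum(dx[m])
    v[4L * b + 2L] <- sum(dy[m])
    v[4L * b + 3L] <- sum(abs(dx[m]))
    v[4L * b + 4L] <- sum(abs(dy[m]))
  }
  nrm <- sqrt(sum(v^2))
  if (nrm <= 1e-9) nrm <- 0          # flat patch up to numerical dust
  if (nrm > 0) v <- v / nrm
  structure(list(v = v, sign = sign, norm = nrm), class = "descriptor")
}

#' Describe a set of interest points
#'
#' @param img An image matrix.
#' @param pts A tibble of points as returned by
#'   [detect_interest_points()] (columns `x`, `y`, `scale`, `sign`).
#' @param params A [descriptor_params()] object.
#' @return A tibble with the point columns plus `norm` and the 64
#'   descriptor components `v0`..`v63`; points whose sampling window
#'   falls entirely outside the image are dropped (point rows and
#'   descriptor rows stay aligned).
#' @export
describe_points <- function(img, pts, params = descriptor_params()) {
  validate_image(img)
  vcols <- paste0("v", 0:63)
  if (nrow(pts) == 0L) {
    empty <- c(list(x = numeric(), y = numeric(), scale = numeric(),
                    sign = numeric(), norm = numeric()),
               setNames(rep(list(numeric()), 64), vcols))
    return(as_tibble(empty))
  }
  ii <- integral_image(img)
  np <- nrow(pts)
  g <- .desc_grid()                      # 400 samples per point
  nsmp <- nrow(g)
  s <- pts$scale * params$window_factor / 20
  if (any(!is.finite(pts$scale)) || any(pts$scale <= 0)) {
    abort("All point scales must be positive.")
  }
  # P x 400 sample geometry (all points at once)
  ux <- outer(s, g$kx + 0.5)
  uy <- outer(s, g$ky + 0.5)
  cx <- round_half_up(pts$x + ux)
  cy <- round_half_up(pts$y + uy)
  r <- pmax(1, round_half_up(pts$scale * params$haar_factor / 2))
  rm <- matrix(r, np, nsmp)
  keep <- cx >= 0 & cx < ii$width & cy >= 0 & cy < ii$height
  w <- exp(-(ux^2 + uy^2) / (2 * (params$sigma_factor * pts$scale)^2))
  dx <- .box_sum(ii, c(cx), c(cy - rm), c(rm), 2 * c(rm)) -
    .box_sum(ii, c(cx - rm), c(cy - rm), c(rm), 2 * c(rm))
  dy <- .box_sum(ii, c(cx - rm), c(cy), 2 * c(rm), c(rm)) -
    .box_sum(ii, c(cx - rm), c(cy - rm), 2 * c(rm), c(rm))
  wdx <- matrix(dx, np, nsmp) * w; wdx[!keep] <- 0
  wdy <- matrix(dy, np, nsmp) * w; wdy[!keep] <- 0
  # subregion accumulation via a 400 x 16 indicator matrix
  sub <- 4L * ((g$ky + 10L) %/% 5L) + ((g$kx + 10L) %/% 5L)
  ind <- outer(sub, 0:15, "==") * 1
  sums <- cbind(wdx %*% ind, wdy %*% ind, abs(wdx) %*% ind, abs(wdy) %*% ind)
  v <- matrix(0, np, 64)
  v[, seq(1, 64, 4)] <- sums[, 1:16]
  v[, seq(2, 64, 4)] <- sums[, 17:32]
  v[, seq(3, 64, 4)] <- sums[, 33:48]
  v[, seq(4, 64, 4)] <- sums[, 49:64]
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm <= 1e-9] <- 0              # flat patches up to numerical dust
  v <- v / ifelse(nrm > 0, nrm, 1)
  ok <- rowSums(keep) > 0                # window entirely outside -> drop
  out <- as_tibble(cbind(
    data.frame(x = pts$x, y = pts$y, scale = pts$scale, sign = pts$sign,
               norm = nrm),
    setNames(as.data.frame(v), vcols)))
  out[ok, ]
}

# Extract the 64-column descriptor matrix from a describe_points tibble.
descriptor_matrix <- function(desc) {
  as.matrix(desc[paste0("v", 0:63)])
}
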