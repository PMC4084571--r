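# Scale-space interest-point detection with box-filter Hessian responses.
#
# The second-order Gaussian derivatives are approximated by piecewise-
# constant box filters evaluated through the integral image, the
# blob response is det(H) ~ Dxx*Dyy - (w*Dxy)^2, and space-scale maxima
# are extracted by 3x3x3 non-maximum suppression with sub-pixel
# quadratic refinement.

#' Detector parameters
#'
#' @param kernel_sizes Strictly increasing odd box-filter side lengths,
#'   each congruent to 3 (mod 6) so the three lobes tile exactly. The
#'   default single octave is 9, 15, 21, 27 pixels.
#' @param weight_w Balance factor `w` in `det(H) = Dxx*Dyy - (w*Dxy)^2`;
#'   0.9 is the standard value compensating the box approximation of the
#'   mixed derivative.
#' @param response_threshold Minimum normalized `det(H)` for a candidate
#'   maximum, on unit-range images.
#' @return A list of class `hessian_params`.
#' @export
hessian_params <- function(kernel_sizes = c(9L, 15L, 21L, 27L),
                           weight_w = 0.9,
                           response_threshold = 1e-4) {
  kernel_sizes <- as.integer(kernel_sizes)
  if (length(kernel_sizes) < 1L || any(diff(kernel_sizes) <= 0L)) {
    abort("`kernel_sizes` must be strictly increasing.")
  }
  if (any(kernel_sizes %% 6L != 3L)) {
    abort("Each kernel size must be congruent to 3 (mod 6), e.g. 9, 15, 21, 27.")
  }
  assert_scalar_number(weight_w, "weight_w")
  if (weight_w <= 0) abort("`weight_w` must be > 0.")
  assert_scalar_number(response_threshold, "response_threshold", lower = 0)
  structure(list(kernel_sizes = kernel_sizes, weight_w = weight_w,
                 response_threshold = response_threshold),
            class = "hessian_params")
}

# Scale attributed to a box kernel of side L: the 9x9 kernel stands for
# a Gaussian with sigma = 1.2, and sigma grows linearly with L.
scale_of_size <- function(L) 1.2 * L / 9

#' Box-filter Hessian response map
#'
#' Evaluates `Dxx`, `Dyy` (two outer lobes weight +1, middle lobe weight
#' -2) and `Dxy` (four single-pixel-gapped corner lobes, weights +/-1)
#' at every pixel via rectangle sums, normalizes each by the kernel area
#' `L^2`, and forms the blob response
#' `det = Dxx*Dyy - (w*Dxy)^2` together with the Laplacian (trace) sign
#' `sign(Dxx + Dyy)` used later to gate matching (`sign(0) = +1`).
#'
#' @param ii An [integral_image()].
#' @param kernel_size Box-filter side `L` (see [hessian_params()]).
#' @param w Balance weight.
#' @return A list of class `response_map`: `det`, `trace_sign` (matrices
#'   the size of the source image), `kernel_size`, `scale`.
#' @export
hessian_response <- function(ii, kernel_size, w = 0.9) {
  stopifnot(inherits(ii, "integral_image"))
  kernel_size <- as.integer(kernel_size)
  if (kernel_size %% 6L != 3L) {
    abort("`kernel_size` must be congruent to 3 (mod 6).")
  }
  if (kernel_size > ii$width || kernel_size > ii$height) {
    abort(sprintf("Kernel %dx%d exceeds the %dx%d image.",
                  kernel_size, kernel_size, ii$width, ii$height))
  }
  ht <- ii$height; wd <- ii$width
  l <- kernel_size %/% 3L
  # Whole-grid clamped lookup at a constant offset: row and column
  # clamps are independent, so one submatrix gather covers every pixel.
  gath <- function(dx, dy) {
    rv <- pmin(pmax(0:(ht - 1L) + dy, -1L), ht - 1L) + 2L
    cv <- pmin(pmax(0:(wd - 1L) + dx, -1L), wd - 1L) + 2L
    ii$.pad[rv, cv, drop = FALSE]
  }
  gbox <- function(ox, oy, bw, bh) {
    gath(ox + bw - 1L, oy + bh - 1L) - gath(ox - 1L, oy + bh - 1L) -
      gath(ox + bw - 1L, oy - 1L) + gath(ox - 1L, oy - 1L)
  }

  # Dyy: full (2l-1) x 3l band minus 3x the middle l-tall lobe
  dyy <- gbox(-(l - 1L), -(3L * l - 1L) %/% 2L, 2L * l - 1L, 3L * l) -
    3 * gbox(-(l - 1L), -(l - 1L) %/% 2L, 2L * l - 1L, l)
  # Dxx: transpose geometry
  dxx <- gbox(-(3L * l - 1L) %/% 2L, -(l - 1L), 3L * l, 2L * l - 1L) -
    3 * gbox(-(l - 1L) %/% 2L, -(l - 1L), l, 2L * l - 1L)
  # Dxy: four l x l lobes around a one-pixel cross gap; +1 where x*y > 0
  dxy <- gbox(-l, -l, l, l) - gbox(1L, -l, l, l) -
    gbox(-l, 1L, l, l) + gbox(1L, 1L, l, l)

  area <- as.numeric(kernel_size)^2
  dxx <- dxx / area; dyy <- dyy / area; dxy <- dxy / area
  det_v <- dxx * dyy - (w * dxy)^2
  tr <- dxx + dyy
  sgn <- matrix(1, ht, wd); sgn[tr < 0] <- -1
  structure(list(det = det_v,
                 trace_sign = sgn,
                 kernel_size = kernel_size,
                 scale = scale_of_size(kernel_size)),
            class = "response_map")
}

#' Detect scale-space interest points
#'
#' Builds one response map per kernel size (a single octave at full
#' resolution), keeps pixels that exceed `response_threshold` and
#' strictly exceed all 26 neighbours in the 3x3x3 space-scale cube
#' (interior scales only), refines each maximum by a 3-d quadratic fit
#' (candidates whose stationary-point offset exceeds 0.5 in any
#' dimension are discarded), and suppresses points closer than half
#' their kernel size to any border.
#'
#' @param img An image matrix.
#' @param params A [hessian_params()] object.
#' @return A tibble with one row per point, columns `x`, `y` (sub-pixel,
#'   0-based), `scale`, `response` (lattice `det(H)`), `sign` (+/-1),
#'   sorted by descending response (ties by `y`, `x`, `scale`).
#' @export
detect_interest_points <- function(img, params = hessian_params()) {
  validate_image(img)
  stopifnot(inherits(params, "hessian_params"))
  ks <- params$kernel_sizes
  if (length(ks) < 3L) {
    abort("At least 3 kernel sizes are needed for space-scale maxima.")
  }
  kmax <- max(ks)
  if (kmax > ncol(img) || kmax > nrow(img)) {
    abort(sprintf(
      "Image %dx%d is smaller than the largest kernel (%dx%d).",
      ncol(img), nrow(img), kmax, kmax))
  }
  ii <- integral_image(img)
  maps <- lapply(ks, function(L) hessian_response(ii, L, params$weight_w))
  ht <- nrow(img); wd <- ncol(img); ns <- length(ks)
  A <- array(0, dim = c(ht, wd, ns))
  S <- array(1, dim = c(ht, wd, ns))
  for (k in seq_len(ns)) {
    A[, , k] <- maps[[k]]$det
    S[, , k] <- maps[[k]]$trace_sign
  }

  # sparse NMS: only pixels above threshold are compared with their 26
  # space-scale neighbours, via flat-index arithmetic into A
  interior <- matrix(FALSE, ht, wd)
  interior[2:(ht - 1L), 2:(wd - 1L)] <- TRUE
  plane <- ht * wd
  cand <- list()
  for (k in 2:(ns - 1L)) {
    flat <- which(A[, , k] > params$response_threshold & interior)
    if (!length(flat)) next
    centre <- A[flat + (k - 1L) * plane]
    keep <- rep(TRUE, length(flat))
    for (dk in -1:1) for (dx in -1:1) for (dy in -1:1) {
      if (dk == 0L && dy == 0L && dx == 0L) next
      off <- dy + dx * ht + (k + dk - 1L) * plane
      keep <- keep & (centre > A[flat + off])
      if (!any(keep)) break
    }
    flat <- flat[keep]
    if (length(flat)) {
      cand[[length(cand) + 1L]] <-
        cbind(row = ((flat - 1L) %% ht) + 1L,
              col = ((flat - 1L) %/% ht) + 1L,
              k = k)
    }
  }
  if (!length(cand)) {
    return(tibble(x = numeric(), y = numeric(), scale = numeric(),
                  response = numeric(), sign = numeric()))
  }
  cand <- do.call(rbind, cand)

  out <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- unname(cand[i, "row"]); c <- unname(cand[i, "col"])
    k <- unname(cand[i, "k"])
    v <- A[(r - 1L):(r + 1L), (c - 1L):(c + 1L), (k - 1L):(k + 1L)]
    g <- c((v[2, 3, 2] - v[2, 1, 2]) / 2,   # d/dx
           (v[3, 2, 2] - v[1, 2, 2]) / 2,   # d/dy
           (v[2, 2, 3] - v[2, 2, 1]) / 2)   # d/ds
    H <- matrix(0, 3, 3)
    H[1, 1] <- v[2, 3, 2] - 2 * v[2, 2, 2] + v[2, 1, 2]
    H[2, 2] <- v[3, 2, 2] - 2 * v[2, 2, 2] + v[1, 2, 2]
    H[3, 3] <- v[2, 2, 3] - 2 * v[2, 2, 2] + v[2, 2, 1]
    H[1, 2] <- H[2, 1] <- (v[3, 3, 2] - v[3, 1, 2] - v[1, 3, 2] + v[1, 1, 2]) / 4
    H[1, 3] <- H[3, 1] <- (v[2, 3, 3] - v[2, 1, 3] - v[2, 3, 1] + v[2, 1, 1]) / 4
    H[2, 3] <- H[3, 2] <- (v[3, 2, 3] - v[1, 2, 3] - v[3, 2, 1] + v[1, 2, 1]) / 4
    off <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(off) || any(!is.finite(off)) || any(abs(off) > 0.5)) next

    x0 <- c - 1L; y0 <- r - 1L            # 0-based lattice coords
    xr <- x0 + off[1]; yr <- y0 + off[2]
    Lk <- ks[k]
    step <- if (off[3] >= 0) ks[k + 1L] - Lk else Lk - ks[k - 1L]
    s <- scale_of_size(Lk + off[3] * step)
    margin <- Lk / 2
    if (xr < margin || xr > (wd - 1L) - margin ||
        yr < margin || yr > (ht - 1L) - margin) next
    out[[i]] <- c(x = xr, y = yr, scale = s,
                  response = v[2, 2, 2], sign = S[r, c, k])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(tibble(x = numeric(), y = numeric(), scale = numeric(),
                  response = numeric(), sign = numeric()))
  }
  pts <- as_tibble(do.call(rbind, out))
  pts[order(-pts$response, pts$y, pts$x, pts$scale), ]
}
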