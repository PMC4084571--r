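# Independent brute-force oracles and fixture builders. Everything here
# computes results directly from definitions (double loops, explicit
# convolution masks, exhaustive search) without touching the package's
# integral-image fast paths.

# Inclusive cumulative sums by direct double loop.
o_integral <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (yy in seq_len(h)) for (xx in seq_len(w)) {
    out[yy, xx] <- sum(img[1:yy, 1:xx])
  }
  out
}

# Rectangle sum by direct summation over the clipped index range
# (0-based half-open rectangle).
o_box_sum <- function(img, x, y, w, h) {
  h0 <- nrow(img); w0 <- ncol(img)
  xs <- max(x, 0):min(x + w - 1, w0 - 1)
  ys <- max(y, 0):min(y + h - 1, h0 - 1)
  if (x + w - 1 < 0 || y + h - 1 < 0 || x > w0 - 1 || y > h0 - 1) return(0)
  sum(img[ys + 1, xs + 1])
}

# Explicit box-filter masks for one kernel size, as dense matrices with
# odd side, centred. Returns list(dxx, dyy, dxy), each a matrix plus its
# centre index attribute.
o_hessian_masks <- function(L) {
  l <- L %/% 3L
  side <- 2L * ((3L * l - 1L) %/% 2L) + 1L  # odd, spans the largest lobe
  ctr <- (side + 1L) %/% 2L
  mk <- function() matrix(0, side, side)
  put <- function(m, x0, y0, w, h, val) {
    m[ctr + y0:(y0 + h - 1), ctr + x0:(x0 + w - 1)] <-
      m[ctr + y0:(y0 + h - 1), ctr + x0:(x0 + w - 1)] + val
    m
  }
  dyy <- mk()
  dyy <- put(dyy, -(l - 1L), -(3L * l - 1L) %/% 2L, 2L * l - 1L, 3L * l, 1)
  dyy <- put(dyy, -(l - 1L), -(l - 1L) %/% 2L, 2L * l - 1L, l, -3)
  dxx <- mk()
  dxx <- put(dxx, -(3L * l - 1L) %/% 2L, -(l - 1L), 3L * l, 2L * l - 1L, 1)
  dxx <- put(dxx, -(l - 1L) %/% 2L, -(l - 1L), l, 2L * l - 1L, -3)
  dxy <- mk()
  dxy <- put(dxy, -l, -l, l, l, 1)
  dxy <- put(dxy, 1L, -l, l, l, -1)
  dxy <- put(dxy, -l, 1L, l, l, -1)
  dxy <- put(dxy, 1L, 1L, l, l, 1)
  list(dxx = dxx, dyy = dyy, dxy = dxy, ctr = ctr)
}

# Direct (zero-padded) convolution of an image with a dense mask.
o_convolve <- function(img, mask, ctr) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (my in seq_len(nrow(mask))) for (mx in seq_len(ncol(mask))) {
    v <- mask[my, mx]
    if (v == 0) next
    oy <- my - ctr; ox <- mx - ctr
    ys <- max(1, 1 - oy):min(h, h - oy)
    xs <- max(1, 1 - ox):min(w, w - ox)
    out[ys, xs] <- out[ys, xs] + v * img[ys + oy, xs + ox]
  }
  out
}

# det(H) map by explicit mask convolution (the oracle counterpart of
# hessian_response).
o_hessian_det <- function(img, L, wgt = 0.9) {
  m <- o_hessian_masks(L)
  a <- L^2
  dxx <- o_convolve(img, m$dxx, m$ctr) / a
  dyy <- o_convolve(img, m$dyy, m$ctr) / a
  dxy <- o_convolve(img, m$dxy, m$ctr) / a
  dxx * dyy - (wgt * dxy)^2
}

# Descriptor by direct per-sample loops following the documented
# sampling scheme (half-up rounding, Haar lobes summed as submatrices).
o_descriptor <- function(img, x, y, s, window_factor = 20, haar_factor = 2,
                         sigma_factor = 3.3) {
  half_up <- function(v) floor(v + 0.5)
  w0 <- ncol(img); h0 <- nrow(img)
  r <- max(1, half_up(s * haar_factor / 2))
  v <- numeric(64)
  for (ky in -10:9) for (kx in -10:9) {
    ux <- (kx + 0.5) * s * window_factor / 20
    uy <- (ky + 0.5) * s * window_factor / 20
    cx <- half_up(x + ux); cy <- half_up(y + uy)
    if (cx < 0 || cx >= w0 || cy < 0 || cy >= h0) next
    wgt <- exp(-(ux^2 + uy^2) / (2 * (sigma_factor * s)^2))
    dx <- o_box_sum(img, cx, cy - r, r, 2 * r) -
      o_box_sum(img, cx - r, cy - r, r, 2 * r)
    dy <- o_box_sum(img, cx - r, cy, 2 * r, r) -
      o_box_sum(img, cx - r, cy - r, 2 * r, r)
    b <- 4 * ((ky + 10) %/% 5) + ((kx + 10) %/% 5)
    v[4 * b + 1] <- v[4 * b + 1] + wgt * dx
    v[4 * b + 2] <- v[4 * b + 2] + wgt * dy
    v[4 * b + 3] <- v[4 * b + 3] + abs(wgt * dx)
    v[4 * b + 4] <- v[4 * b + 4] + abs(wgt * dy)
  }
  nrm <- sqrt(sum(v^2))
  list(v = if (nrm > 0) v / nrm else v, norm = nrm)
}

# Exhaustive sign-gated ratio-test matcher over all pairs.
o_match <- function(q_mat, t_mat, q_sign, t_sign, ratio = 0.7,
                    single_max = 0.25) {
  out <- NULL
  for (i in seq_len(nrow(q_mat))) {
    cand <- which(t_sign == q_sign[i])
    if (!length(cand)) next
    d <- sqrt(colSums((t(t_mat[cand, , drop = FALSE]) - q_mat[i, ])^2))
    o <- order(d)
    keep <- if (length(cand) == 1L) d[o[1]] < single_max else
      d[o[1]] < ratio * d[o[2]]
    if (keep) out <- rbind(out, c(i, cand[o[1]], d[o[1]]))
  }
  if (is.null(out)) {
    return(data.frame(query_index = integer(), train_index = integer(),
                      distance = numeric()))
  }
  out <- data.frame(query_index = out[, 1], train_index = out[, 2],
                    distance = out[, 3])
  out[order(out$distance, out$query_index), , drop = FALSE]
}

# Image with isotropic Gaussian blobs at given centres (0-based coords).
gauss_blobs <- function(width, height, centers, sigma, amp = 0.3,
                        background = 0.4) {
  img <- matrix(background, height, width)
  X <- matrix(rep(0:(width - 1), each = height), height, width)
  Y <- matrix(rep(0:(height - 1), times = width), height, width)
  if (length(sigma) == 1) sigma <- rep(sigma, nrow(centers))
  if (length(amp) == 1) amp <- rep(amp, nrow(centers))
  for (i in seq_len(nrow(centers))) {
    img <- img + amp[i] *
      exp(-((X - centers[i, 1])^2 + (Y - centers[i, 2])^2) / (2 * sigma[i]^2))
  }
  img
}

rand_img <- function(seed, h, w) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

# Integer-translate an image on a constant background (no resampling).
shift_img <- function(img, dx, dy, fill = 0.4) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(fill, h, w)
  xs <- max(1, 1 + dx):min(w, w + dx)
  ys <- max(1, 1 + dy):min(h, h + dy)
  out[ys, xs] <- img[ys - dy, xs - dx]
  out
}
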