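# Sign-gated nearest-neighbour descriptor matching and seeded RANSAC
# homography estimation.
#
# Candidate pairs are restricted to descriptors with the same Laplacian
# sign (bright-on-dark blobs never match dark-on-bright ones), then the
# smallest Euclidean distance wins subject to a Lowe-style ratio test
# against the second-nearest candidate.

#' Matching and RANSAC parameters
#'
#' @param ratio Nearest/second-nearest distance ratio bound for a "good
#'   match" (default 0.7).
#' @param single_candidate_max Absolute distance bound applied when only
#'   one same-sign candidate exists (default 0.25).
#' @param ransac_threshold Symmetric reprojection error bound in pixels
#'   (default 3).
#' @param ransac_max_iter Maximum RANSAC iterations (default 2000; the
#'   loop stops earlier once the consensus makes further sampling
#'   pointless at 99% confidence).
#' @param rng_seed Seed for the RANSAC sampler; identical seeds give
#'   bit-identical inlier masks.
#' @return A list of class `match_params`.
#' @export
match_params <- function(ratio = 0.7, single_candidate_max = 0.25,
                         ransac_threshold = 3.0, ransac_max_iter = 2000L,
                         rng_seed = 1L) {
  assert_scalar_number(ratio, "ratio")
  if (ratio <= 0 || ratio >= 1) abort("`ratio` must satisfy 0 < ratio < 1.")
  assert_scalar_number(single_candidate_max, "single_candidate_max", lower = 0)
  assert_scalar_number(ransac_threshold, "ransac_threshold")
  if (ransac_threshold <= 0) abort("`ransac_threshold` must be > 0.")
  if (ransac_max_iter < 1) abort("`ransac_max_iter` must be >= 1.")
  structure(list(ratio = ratio, single_candidate_max = single_candidate_max,
                 ransac_threshold = ransac_threshold,
                 ransac_max_iter = as.integer(ransac_max_iter),
                 rng_seed = as.integer(rng_seed)),
            class = "match_params")
}

#' Match descriptors between a template and a frame
#'
#' For each template descriptor, candidates are the frame descriptors
#' with equal Laplacian sign; the nearest is kept as a good match iff
#' its distance is below `ratio` times the second-nearest distance
#' (or below `single_candidate_max` when only one candidate exists).
#'
#' @param template,frame Descriptor tibbles from [describe_points()].
#' @param params A [match_params()] object.
#' @return A tibble with columns `query_index` (row in `template`),
#'   `train_index` (row in `frame`), `distance`, sorted by ascending
#'   distance (ties by `query_index`).
#' @export
match_descriptors <- function(template, frame, params = match_params()) {
  empty <- tibble(query_index = integer(), train_index = integer(),
                  distance = numeric())
  nq <- nrow(template); nt <- nrow(frame)
  if (nq == 0L || nt == 0L) return(empty)
  Q <- descriptor_matrix(template); M <- descriptor_matrix(frame)
  d2 <- outer(rowSums(Q^2), rowSums(M^2), "+") - 2 * tcrossprod(Q, M)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  same <- outer(template$sign, frame$sign, "==")
  qi <- integer(); ti <- integer(); dist <- numeric()
  for (i in seq_len(nq)) {
    cand <- which(same[i, ])
    if (!length(cand)) next
    di <- d[i, cand]
    o <- order(di)
    best <- di[o[1]]
    keep <- if (length(cand) == 1L) {
      best < params$single_candidate_max
    } else {
      best < params$ratio * di[o[2]]
    }
    if (keep) {
      qi <- c(qi, i); ti <- c(ti, cand[o[1]]); dist <- c(dist, best)
    }
  }
  out <- tibble(query_index = qi, train_index = ti, distance = dist)
  out[order(out$distance, out$query_index), ]
}

# --- homography helpers ----------------------------------------------

#' Apply a homography to points
#'
#' @param m A 3x3 homography matrix (template -> frame).
#' @param pts Data frame or matrix with columns/cols `x`, `y`.
#' @return A tibble with transformed `x`, `y`.
#' @export
apply_homography <- function(m, pts) {
  if (is.data.frame(pts)) pts <- cbind(pts$x, pts$y)
  p <- m %*% rbind(t(pts), 1)
  tibble(x = p[1, ] / p[3, ], y = p[2, ] / p[3, ])
}

# Direct linear transform for >= 4 correspondences, with Hartley
# normalization for the least-squares (> 4 point) case. Returns a 3x3
# matrix normalized to m[3,3] = 1, or NULL when degenerate.
fit_homography_dlt <- function(src, dst) {
  n <- nrow(src)
  if (n < 4L) return(NULL)
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    sc <- mean(sqrt(rowSums(sweep(p, 2, ctr)^2)))
    if (!is.finite(sc) || sc < 1e-12) return(NULL)
    s <- sqrt(2) / sc
    T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1),
                3, 3, byrow = TRUE)
    list(p = sweep(p, 2, ctr) * s, T = T)
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  if (is.null(ns) || is.null(nd)) return(NULL)
  x <- ns$p[, 1]; y <- ns$p[, 2]; u <- nd$p[, 1]; v <- nd$p[, 2]
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  sv <- tryCatch(svd(A, nu = 0, nv = 9), error = function(e) NULL)
  if (is.null(sv)) return(NULL)
  h <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  m <- solve(nd$T) %*% h %*% ns$T
  if (abs(m[3, 3]) < 1e-12) return(NULL)
  m <- m / m[3, 3]
  if (any(!is.finite(m))) return(NULL)
  m
}

# TRUE when any 3 of the points are (nearly) collinear.
any_collinear <- function(p, tol = 1e-6) {
  n <- nrow(p)
  cmb <- utils::combn(n, 3)
  for (j in seq_len(ncol(cmb))) {
    a <- p[cmb[1, j], ]; b <- p[cmb[2, j], ]; c <- p[cmb[3, j], ]
    area <- abs((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    if (area < tol) return(TRUE)
  }
  FALSE
}

# Symmetric reprojection error: mean of forward and backward Euclidean
# residuals per correspondence.
symmetric_error <- function(m, src, dst) {
  mi <- tryCatch(solve(m), error = function(e) NULL)
  if (is.null(mi)) return(rep(Inf, nrow(src)))
  f <- apply_homography(m, src)
  b <- apply_homography(mi, dst)
  ef <- sqrt((f$x - dst[, 1])^2 + (f$y - dst[, 2])^2)
  eb <- sqrt((b$x - src[, 1])^2 + (b$y - src[, 2])^2)
  (ef + eb) / 2
}

#' Estimate a homography from matches by seeded RANSAC
#'
#' Each iteration samples 4 distinct matches, solves the direct linear
#' transform, and counts matches whose symmetric reprojection error is
#' below `ransac_threshold`; the best consensus wins and the final
#' matrix is re-estimated by least squares on all inliers. Degenerate
#' samples (three collinear points) are skipped.
#'
#' @param matches A tibble from [match_descriptors()].
#' @param template_pts,frame_pts Point tables aligned with the
#'   descriptor tibbles the matches index into (columns `x`, `y`).
#' @param params A [match_params()] object (threshold, iterations, seed).
#' @return An object of class `homography` (fields `m`, `inlier_mask`,
#'   `n_inliers`), or `NULL` when fewer than 4 matches exist or no
#'   4-inlier consensus is found.
#' @export
estimate_homography <- function(matches, template_pts, frame_pts,
                                params = match_params()) {
  n <- nrow(matches)
  if (n < 4L) return(NULL)
  src <- cbind(template_pts$x[matches$query_index],
               template_pts$y[matches$query_index])
  dst <- cbind(frame_pts$x[matches$train_index],
               frame_pts$y[matches$train_index])
  best_mask <- NULL; best_n <- 0L; best_err <- Inf
  with_seed(params$rng_seed, {
    max_iter <- params$ransac_max_iter
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      pick <- sample.int(n, 4L)
      if (any_collinear(src[pick, , drop = FALSE]) ||
          any_collinear(dst[pick, , drop = FALSE])) next
      m <- fit_homography_dlt(src[pick, , drop = FALSE],
                              dst[pick, , drop = FALSE])
      if (is.null(m)) next
      err <- symmetric_error(m, src, dst)
      mask <- err < params$ransac_threshold
      ni <- sum(mask)
      tot <- sum(err[mask])
      if (ni > best_n || (ni == best_n && tot < best_err)) {
        best_n <- ni; best_mask <- mask; best_err <- tot
        # adaptive stopping: iterations needed for 99% confidence of one
        # outlier-free sample at the observed inlier ratio
        wi <- ni / n
        if (wi > 0) {
          need <- log(0.01) / log(max(1e-12, 1 - wi^4))
          max_iter <- min(max_iter, max(it, ceiling(need)))
        }
      }
    }
  })
  if (is.null(best_mask) || best_n < 4L) return(NULL)
  m <- fit_homography_dlt(src[best_mask, , drop = FALSE],
                          dst[best_mask, , drop = FALSE])
  if (is.null(m)) return(NULL)
  structure(list(m = m, inlier_mask = best_mask, n_inliers = best_n,
                 n_matches = n),
            class = "homography")
}

#' @export
print.homography <- function(x, ...) {
  cat(sprintf("<homography: %d/%d inliers>\n", x$n_inliers, x$n_matches))
  print(round(x$m, 6))
  invisible(x)
}

#' Tidy a homography into one row per matrix entry
#'
#' @param x A `homography` object.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `value`.
#' @method tidy homography
#' @export
tidy.homography <- function(x, ...) {
  tibble(row = rep(1:3, each = 3), col = rep(1:3, 3),
         value = as.numeric(t(x$m)))
}

#' One-row summary of a homography fit
#'
#' @param x A `homography` object.
#' @param ... Unused.
#' @return A tibble with `n_matches`, `n_inliers`, `inlier_rate`, and
#'   the translation components `tx` (`m[1,3]`), `ty` (`m[2,3]`).
#' @method glance homography
#' @export
glance.homography <- function(x, ...) {
  tibble(n_matches = x$n_matches, n_inliers = x$n_inliers,
         inlier_rate = x$n_inliers / x$n_matches,
         tx = x$m[1, 3], ty = x$m[2, 3])
}
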