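# ROI tracking and fluorescence mask overlay.
#
# A tracker holds a transmission template ("light off"), a fluorescence
# mask acquired once ("light on"), and a user ROI. Each live frame is
# matched against the cached ROI descriptors, the ROI is re-located via
# a RANSAC homography, and the mask is warped and alpha-blended onto
# the frame — so fluorescence is displayed without re-exciting the
# tissue.

#' Blending specification
#'
#' @param alpha Opacity of the overlay in `[0, 1]`; the composite is
#'   `alpha * overlay + (1 - alpha) * frame`.
#' @return A list of class `blend_spec`.
#' @export
blend_spec <- function(alpha = 0.5) {
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  structure(list(alpha = alpha), class = "blend_spec")
}

# Accept a homography object or a bare 3x3 matrix.
as_homography_matrix <- function(h) {
  if (inherits(h, "homography")) return(h$m)
  if (is.matrix(h) && all(dim(h) == c(3L, 3L))) return(h)
  abort("`h` must be a homography object or a 3x3 matrix.")
}

# Bilinear sampling of img at sub-pixel (sx, sy) (0-based, vectorized).
# outside = "zero": samples beyond the grid contribute 0;
# outside = "clamp": coordinates are clamped to the grid (replicate edge).
.bilinear_sample <- function(img, sx, sy, outside = "zero") {
  ht <- nrow(img); wd <- ncol(img)
  if (outside == "clamp") {
    sx <- pmax(pmin(sx, wd - 1), 0)
    sy <- pmax(pmin(sy, ht - 1), 0)
  }
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  pick <- function(xi, yi) {
    ok <- xi >= 0 & xi <= wd - 1 & yi >= 0 & yi <= ht - 1
    v <- numeric(length(xi))
    v[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  (1 - fx) * (1 - fy) * pick(x0, y0) +
    fx * (1 - fy) * pick(x0 + 1, y0) +
    (1 - fx) * fy * pick(x0, y0 + 1) +
    fx * fy * pick(x0 + 1, y0 + 1)
}

# TRUE for lattice points (px, py) inside (or on) the convex quad
# given as a 4x2 matrix of corners in order.
.in_quad <- function(px, py, quad) {
  # orientation from the signed area
  xs <- quad[, 1]; ys <- quad[, 2]
  area2 <- sum(xs * ys[c(2:4, 1)] - xs[c(2:4, 1)] * ys)
  s <- if (area2 >= 0) 1 else -1
  inside <- rep(TRUE, length(px))
  for (e in 1:4) {
    a <- quad[e, ]; b <- quad[if (e == 4L) 1L else e + 1L, ]
    cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    inside <- inside & (s * cr >= -1e-9)
  }
  inside
}

#' Alpha-blend an overlay onto a frame
#'
#' Inside `region` the output is
#' `alpha * overlay + (1 - alpha) * frame` per pixel (the overlay must
#' already be registered to frame coordinates); outside, the frame
#' passes through untouched. The result is clipped to `[0, 1]`.
#'
#' @param frame,overlay Image matrices of identical size.
#' @param spec A [blend_spec()] (or a bare alpha value).
#' @param region `"full"`, or a 4x2 matrix of quad corners (x, y) in
#'   order, typically the warped ROI.
#' @return The composited image matrix.
#' @export
alpha_blend <- function(frame, overlay, spec = blend_spec(), region = "full") {
  validate_image(frame); validate_image(overlay)
  if (!all(dim(frame) == dim(overlay))) {
    abort("`frame` and `overlay` must share dimensions.")
  }
  if (!inherits(spec, "blend_spec")) spec <- blend_spec(spec)
  a <- spec$alpha
  blended <- a * overlay + (1 - a) * frame
  if (identical(region, "full")) {
    out <- blended
  } else {
    if (!is.matrix(region) || !all(dim(region) == c(4L, 2L))) {
      abort("`region` must be \"full\" or a 4x2 corner matrix.")
    }
    px <- rep(0:(ncol(frame) - 1L), each = nrow(frame))
    py <- rep(0:(nrow(frame) - 1L), times = ncol(frame))
    m <- matrix(.in_quad(px, py, region), nrow(frame), ncol(frame))
    out <- frame
    out[m] <- blended[m]
  }
  pmax(pmin(out, 1), 0)
}

#' Warp a mask into frame coordinates
#'
#' Inverse-mapping warp with bilinear interpolation: each output pixel
#' looks up `h^-1 (x, y)` in the mask; pixels mapping outside the mask
#' are set to 0.
#'
#' @param mask An image matrix in template coordinates.
#' @param h A homography (template -> frame) or 3x3 matrix.
#' @param out_shape `c(height, width)` of the output (defaults to the
#'   mask's own shape).
#' @param roi Optional [rect()] in template coordinates; when given,
#'   its warped corner quad is returned alongside.
#' @return A list with `image` (the warped mask) and `quad` (4x2 corner
#'   matrix, or `NULL` when `roi` is absent).
#' @export
warp_mask <- function(mask, h, out_shape = dim(mask), roi = NULL) {
  validate_image(mask)
  m <- as_homography_matrix(h)
  mi <- tryCatch(solve(m), error = function(e) NULL)
  if (is.null(mi) || any(!is.finite(mi))) {
    abort("The homography matrix is not invertible.")
  }
  ht <- out_shape[1]; wd <- out_shape[2]
  px <- rep(0:(wd - 1L), each = ht)
  py <- rep(0:(ht - 1L), times = wd)
  src <- apply_homography(mi, cbind(px, py))
  out <- matrix(.bilinear_sample(mask, src$x, src$y, outside = "zero"),
                ht, wd)
  quad <- if (!is.null(roi)) {
    corners <- roi_corners(roi)
    p <- apply_homography(m, corners)
    cbind(p$x, p$y)
  }
  list(image = out, quad = quad)
}

# Geometric corners of a rect, in order TL, TR, BR, BL.
roi_corners <- function(roi) {
  data.frame(x = c(roi$x, roi$x + roi$w, roi$x + roi$w, roi$x),
             y = c(roi$y, roi$y, roi$y + roi$h, roi$y + roi$h))
}

#' Create a tracker
#'
#' Caches interest points and descriptors of the ROI patch of the
#' template frame (points are detected on the ROI crop, then expressed
#' in template coordinates; descriptors are sampled on the full
#' template so their windows may extend beyond the ROI).
#'
#' @param template Transmission image at mask-acquisition time
#'   ("light off").
#' @param mask Fluorescence image co-registered with `template`
#'   ("light on"). May be `NULL` when only tracking (no overlay) is
#'   needed.
#' @param roi A single-row [rect()] in template coordinates.
#' @param hessian,matcher,descriptor Parameter objects.
#' @param min_matches Minimum good matches for the ROI to be declared
#'   present (default 4, the homography minimum).
#' @param alpha Default blending opacity.
#' @return A list of class `tracker_state`.
#' @export
tracker_state <- function(template, mask, roi,
                          hessian = hessian_params(),
                          matcher = match_params(),
                          descriptor = descriptor_params(),
                          min_matches = 4L, alpha = 0.5) {
  validate_image(template)
  if (!is.null(mask)) {
    validate_image(mask)
    if (!all(dim(mask) == dim(template))) {
      abort("`mask` and `template` must share dimensions.")
    }
  }
  if (nrow(roi) != 1L) abort("`roi` must be a single rectangle.")
  if (roi$x < 0 || roi$y < 0 ||
      roi$x + roi$w > ncol(template) || roi$y + roi$h > nrow(template)) {
    abort("`roi` must lie within the template bounds.")
  }
  patch <- template[(roi$y + 1):(roi$y + roi$h),
                    (roi$x + 1):(roi$x + roi$w), drop = FALSE]
  pts <- detect_interest_points(patch, hessian)
  pts$x <- pts$x + roi$x
  pts$y <- pts$y + roi$y
  desc <- describe_points(template, pts, descriptor)
  if (nrow(desc) == 0L) {
    warn("No interest points found in the ROI; the tracker will never report presence.")
  }
  structure(list(template = template, mask = mask, roi = roi,
                 template_points = desc[c("x", "y", "scale", "sign")],
                 template_descriptors = desc,
                 hessian = hessian, matcher = matcher,
                 descriptor = descriptor,
                 min_matches = as.integer(min_matches), alpha = alpha),
            class = "tracker_state")
}

#' Track the ROI in one frame
#'
#' Detects and describes the full frame, matches against the cached ROI
#' descriptors, and estimates a template-to-frame homography. The ROI
#' is declared present when a homography is found and the number of
#' good matches reaches `min_matches`. Tracking failure yields
#' `present = FALSE`, never an error.
#'
#' @param state A [tracker_state()].
#' @param frame An image matrix.
#' @param min_matches Override of the state's presence threshold.
#' @return A list of class `track_result`: `n_keypoints`, `n_good`,
#'   `present`, `homography` (or `NULL`), `roi_corners` (4x2 matrix or
#'   `NULL`).
#' @export
track_frame <- function(state, frame, min_matches = state$min_matches) {
  stopifnot(inherits(state, "tracker_state"))
  res <- tryCatch({
    validate_image(frame)
    pts <- detect_interest_points(frame, state$hessian)
    desc <- describe_points(frame, pts, state$descriptor)
    matches <- match_descriptors(state$template_descriptors, desc,
                                 state$matcher)
    h <- estimate_homography(matches, state$template_points,
                             desc, state$matcher)
    present <- !is.null(h) && nrow(matches) >= min_matches
    corners <- if (present) {
      p <- apply_homography(h$m, roi_corners(state$roi))
      cbind(p$x, p$y)
    }
    list(n_keypoints = nrow(desc), n_good = nrow(matches),
         present = present, homography = if (present) h,
         roi_corners = corners)
  }, error = function(e) {
    list(n_keypoints = 0L, n_good = 0L, present = FALSE,
         homography = NULL, roi_corners = NULL)
  })
  structure(res, class = "track_result")
}

#' Track a sequence and composite the fluorescence overlay
#'
#' Per frame: [track_frame()]; when the ROI is present, the mask is
#' warped through the recovered homography and alpha-blended within the
#' warped ROI quad (or over the full frame). Frames where the ROI is
#' absent pass through unblended; frames whose dimensions differ from
#' the first are marked absent with a warning.
#'
#' @param state A [tracker_state()] with a non-`NULL` mask.
#' @param frames List of image matrices, in order.
#' @param spec A [blend_spec()].
#' @param region `"quad"` (blend inside the warped ROI only, the
#'   default) or `"full"`.
#' @return A list of class `track_run`: `results` (tibble, one row per
#'   frame: `frame`, `n_keypoints`, `n_good`, `present`, `h00`..`h22`,
#'   `c0x`..`c3y`) and `composites` (list of images).
#' @export
run_tracking_sequence <- function(state, frames, spec = blend_spec(),
                                  region = c("quad", "full")) {
  stopifnot(inherits(state, "tracker_state"))
  region <- match.arg(region)
  if (!length(frames)) abort("`frames` must contain at least one image.")
  if (is.null(state$mask)) abort("The tracker has no fluorescence mask.")
  ref_dim <- dim(frames[[1]])
  rows <- vector("list", length(frames))
  comps <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!all(dim(f) == ref_dim)) {
      warn(sprintf("Frame %d has mismatched dimensions; marked absent.", i))
      tr <- structure(list(n_keypoints = 0L, n_good = 0L, present = FALSE,
                           homography = NULL, roi_corners = NULL),
                      class = "track_result")
    } else {
      tr <- track_frame(state, f)
    }
    if (tr$present) {
      wm <- warp_mask(state$mask, tr$homography, dim(f), roi = state$roi)
      reg <- if (region == "quad") wm$quad else "full"
      comps[[i]] <- alpha_blend(f, wm$image, spec, reg)
    } else {
      comps[[i]] <- f
    }
    hvec <- if (tr$present) as.numeric(t(tr$homography$m)) else rep(NA_real_, 9)
    cvec <- if (tr$present) as.numeric(t(tr$roi_corners)) else rep(NA_real_, 8)
    rows[[i]] <- c(frame = i - 1, n_keypoints = tr$n_keypoints,
                   n_good = tr$n_good, present = as.numeric(tr$present),
                   setNames(hvec, paste0("h", c(t(outer(0:2, 0:2, paste0))))),
                   setNames(cvec, paste0("c", rep(0:3, each = 2), c("x", "y"))))
  }
  results <- as_tibble(do.call(rbind, rows))
  results$present <- results$present == 1
  structure(list(results = results, composites = comps),
            class = "track_run")
}

#' @export
print.track_run <- function(x, ...) {
  cat(sprintf("<track_run: %d frames, %d present>\n",
              nrow(x$results), sum(x$results$present)))
  invisible(x)
}

#' Per-frame tracking results as a tibble
#'
#' @param x A `track_run` object.
#' @param ... Unused.
#' @return The per-frame results tibble.
#' @method tidy track_run
#' @export
tidy.track_run <- function(x, ...) x$results

#' One-row summary of a tracking run
#'
#' @param x A `track_run` object.
#' @param ... Unused.
#' @return A tibble with `n_frames`, `n_present`, `mean_good`.
#' @method glance track_run
#' @export
glance.track_run <- function(x, ...) {
  tibble(n_frames = nrow(x$results),
         n_present = sum(x$results$present),
         mean_good = mean(x$results$n_good))
}
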