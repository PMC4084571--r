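# ROI tracking, mask warping and alpha blending.

test_that("alpha blending honours the opacity extremes and the mean case", {
  set.seed(3)
  f <- matrix(runif(30 * 40), 30, 40)
  o <- matrix(runif(30 * 40), 30, 40)
  expect_equal(alpha_blend(f, o, blend_spec(0)), f)
  expect_equal(alpha_blend(f, o, blend_spec(1)), o)
  expect_equal(alpha_blend(matrix(0.2, 5, 5), matrix(0.8, 5, 5),
                           blend_spec(0.5)),
               matrix(0.5, 5, 5))
  expect_error(blend_spec(1.2), "alpha")
})

test_that("blending is convex and confined to the region", {
  set.seed(4)
  f <- matrix(runif(40 * 40), 40, 40)
  o <- matrix(runif(40 * 40), 40, 40)
  for (a in c(0.25, 0.5, 0.9)) {
    out <- alpha_blend(f, o, blend_spec(a))
    expect_true(all(out >= pmin(f, o) - 1e-12))
    expect_true(all(out <= pmax(f, o) + 1e-12))
  }
  quad <- cbind(c(10, 25, 25, 10), c(5, 5, 20, 20))
  out <- alpha_blend(f, o, blend_spec(0.5), region = quad)
  inside <- matrix(FALSE, 40, 40)
  inside[6:21, 11:26] <- TRUE
  expect_equal(out[!inside], f[!inside])  # pass-through outside the quad
  expect_equal(out[16, 16], 0.5 * o[16, 16] + 0.5 * f[16, 16])
})

test_that("warping is exact for identity and integer translations", {
  set.seed(6)
  mask <- matrix(runif(50 * 60), 50, 60)
  id <- diag(3)
  expect_equal(warp_mask(mask, id)$image, mask, tolerance = 1e-6)
  tr <- matrix(c(1, 0, 5, 0, 1, 7, 0, 0, 1), 3, 3, byrow = TRUE)
  got <- warp_mask(mask, tr)$image
  want <- matrix(0, 50, 60)
  want[8:50, 6:60] <- mask[1:43, 1:55]
  expect_equal(got, want, tolerance = 1e-9)
  # ROI corners ride along exactly
  w <- warp_mask(mask, tr, roi = rect(10, 12, 20, 15))
  expect_equal(w$quad[, 1], c(10, 30, 30, 10) + 5)
  expect_equal(w$quad[, 2], c(12, 12, 27, 27) + 7)
  expect_error(warp_mask(mask, matrix(0, 3, 3)), "invertible")
})

# Shared fixture: a culture-like scene, its mask, ROI and tracker.
local_tracker <- local({
  sc <- synth_scene(scene_spec(rng_seed = 42))
  spec <- scene_spec(rng_seed = 42)
  mask <- synth_fluorescence_mask(sc$truth, spec)
  roi <- neurotrackr:::.roi_densest(sc$truth, 140, 155, 640, 480)
  list(sc = sc, spec = spec, mask = mask, roi = roi,
       state = tracker_state(sc$image, mask, roi))
})

test_that("the template tracks itself at the identity", {
  tr <- track_frame(local_tracker$state, local_tracker$sc$image)
  expect_true(tr$present)
  expect_gt(tr$n_good, 4)
  corners <- neurotrackr:::roi_corners(local_tracker$roi)
  err <- max(sqrt((tr$roi_corners[, 1] - corners$x)^2 +
                    (tr$roi_corners[, 2] - corners$y)^2))
  expect_lt(err, 0.5)
  # projective terms stay negligible for a pure self-registration
  expect_lt(max(abs(tr$homography$m[3, 1:2])), 1e-2)
})

test_that("unrelated random texture yields absence, not an error", {
  set.seed(77)
  noise <- matrix(runif(480 * 640), 480, 640)
  tr <- track_frame(local_tracker$state, noise)
  expect_false(tr$present)
  expect_null(tr$roi_corners)
  # so does a frame smaller than the detector kernels
  tr2 <- track_frame(local_tracker$state, matrix(0.5, 10, 10))
  expect_false(tr2$present)
})

test_that("a tracked sequence recovers planted drifts and composites the mask", {
  st <- local_tracker$state
  roi <- local_tracker$roi
  drifts <- list(c(6.5, -3.25), c(24, -13), c(-18.5, 11.75))
  seqd <- synth_sequence(local_tracker$sc, drifts, noise_sigma = 0.02,
                         roi = roi, rng_seed = 7)
  run <- run_tracking_sequence(st, seqd$frames)
  res <- tidy(run)
  expect_equal(nrow(res), 3)
  expect_true(all(res$present))
  ctr <- c(roi$x + roi$w / 2, roi$y + roi$h / 2)
  for (i in 1:3) {
    h <- matrix(as.numeric(res[i, paste0("h", c(t(outer(0:2, 0:2, paste0))))]),
                3, 3, byrow = TRUE)
    got <- apply_homography(h, data.frame(x = ctr[1], y = ctr[2]))
    want <- ctr + drifts[[i]]
    expect_lt(sqrt((got$x - want[1])^2 + (got$y - want[2])^2), 0.5)
  }
  # composites: fluorescence shows inside the warped quad only
  comp <- run$composites[[1]]
  frame <- seqd$frames[[1]]
  quad <- cbind(as.numeric(res[1, c("c0x", "c1x", "c2x", "c3x")]),
                as.numeric(res[1, c("c0y", "c1y", "c2y", "c3y")]))
  outside <- matrix(TRUE, 480, 640)
  xr <- range(quad[, 1]); yr <- range(quad[, 2])
  outside[max(1, floor(yr[1]) - 1):min(480, ceiling(yr[2]) + 2),
          max(1, floor(xr[1]) - 1):min(640, ceiling(xr[2]) + 2)] <- FALSE
  expect_equal(comp[outside], frame[outside])
  g <- glance(run)
  expect_equal(g$n_present, 3)
})

test_that("a blank frame passes through unblended between tracked frames", {
  st <- local_tracker$state
  seqd <- synth_sequence(local_tracker$sc, list(c(0, 0), c(3.5, 2.25)),
                         noise_sigma = 0.01, roi = local_tracker$roi,
                         rng_seed = 3)
  blank <- matrix(0.5, 480, 640)
  run <- run_tracking_sequence(st, list(seqd$frames[[1]], blank,
                                        seqd$frames[[2]]))
  expect_equal(run$results$present, c(TRUE, FALSE, TRUE))
  expect_identical(run$composites[[2]], blank)
  # mismatched dimensions are flagged absent with a warning
  expect_warning(
    run2 <- run_tracking_sequence(st, list(seqd$frames[[1]],
                                           matrix(0.5, 100, 100))),
    "mismatch")
  expect_equal(run2$results$present, c(TRUE, FALSE))
})

test_that("spot centres brighten when the mask is blended over the scene", {
  sc <- local_tracker$sc
  mask <- local_tracker$mask
  blend <- alpha_blend(sc$image, mask, blend_spec(0.5))
  n_brighter <- 0
  for (i in sc$truth$fluorescent_subset) {
    px <- round(sc$truth$cell_centers$y[i]) + 1
    py <- round(sc$truth$cell_centers$x[i]) + 1
    # convexity: blending a brighter overlay brightens the pixel; the
    # few somata whose core already saturates stay between the two
    if (mask[px, py] > sc$image[px, py]) {
      expect_gt(blend[px, py], sc$image[px, py])
      n_brighter <- n_brighter + 1
    } else {
      expect_gte(blend[px, py], min(mask[px, py], sc$image[px, py]) - 1e-9)
    }
  }
  expect_gt(n_brighter, 0)
})
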