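# Scale-space box-filter blob detection.

test_that("hessian_response matches the explicit mask-convolution oracle", {
  # flat field: the determinant vanishes away from the zero-padded
  # border (border responses exist by design and are suppressed at the
  # detection stage)
  flat <- matrix(0.7, 40, 40)
  rm <- hessian_response(integral_image(flat), 9)
  expect_lt(max(abs(rm$det[6:35, 6:35])), 1e-12)
  # every default scale on random images
  set.seed(21)
  for (L in c(9L, 15L, 21L, 27L)) {
    for (rep in 1:3) {
      img <- matrix(runif(33 * 33), 33, 33)
      got <- hessian_response(integral_image(img), L, w = 0.9)
      want <- o_hessian_det(img, L, 0.9)
      expect_equal(got$det, want, tolerance = 1e-9)
    }
  }
  expect_error(hessian_response(integral_image(matrix(0, 10, 10)), 15),
               "15")
  expect_error(hessian_response(integral_image(flat), 12), "mod 6")
})

test_that("the 9x9 response peaks at the centre of a Gaussian blob", {
  img <- gauss_blobs(64, 64, cbind(31.5, 31.5), sigma = 2.4, background = 0)
  rm <- hessian_response(integral_image(img), 9)
  idx <- which(rm$det == max(rm$det), arr.ind = TRUE)[1, ]
  expect_lt(abs((idx["col"] - 1) - 31.5), 1)
  expect_lt(abs((idx["row"] - 1) - 31.5), 1)
})

test_that("trace sign separates bright and dark blobs", {
  bright <- gauss_blobs(48, 48, cbind(24, 24), sigma = 2.5, amp = 0.3)
  dark <- gauss_blobs(48, 48, cbind(24, 24), sigma = 2.5, amp = -0.3)
  pb <- detect_interest_points(bright)
  pd <- detect_interest_points(dark)
  expect_gt(nrow(pb), 0)
  expect_gt(nrow(pd), 0)
  # bright-on-dark blob: negative Laplacian; dark-on-bright: positive
  expect_true(all(pb$sign == -1))
  expect_true(all(pd$sign == 1))
})

test_that("detection finds well-separated blobs and nothing on flat fields", {
  expect_equal(nrow(detect_interest_points(matrix(0.5, 64, 64))), 0)
  centers <- cbind(c(30, 90, 150, 60, 120), c(40, 30, 50, 100, 110))
  img <- gauss_blobs(180, 140, centers, sigma = 2.5)
  pts <- detect_interest_points(img)
  expect_equal(nrow(pts), 5)
  for (i in 1:5) {
    d <- min(sqrt((pts$x - centers[i, 1])^2 + (pts$y - centers[i, 2])^2))
    expect_lt(d, 1)
  }
  # sorted by descending response
  expect_true(all(diff(pts$response) <= 0))
})

test_that("every returned point is a strict 26-neighbour space-scale maximum", {
  img <- gauss_blobs(120, 100, cbind(c(35, 80), c(45, 60)), sigma = c(2.3, 2.8))
  p <- hessian_params()
  ii <- integral_image(img)
  maps <- lapply(p$kernel_sizes, function(L) hessian_response(ii, L, p$weight_w))
  A <- simplify2array(lapply(maps, function(m) m$det))
  pts <- detect_interest_points(img, p)
  expect_gt(nrow(pts), 0)
  for (i in seq_len(nrow(pts))) {
    # locate the lattice cell through its (unique) lattice response
    hit <- which(A == pts$response[i], arr.ind = TRUE)
    expect_equal(nrow(hit), 1)
    r0 <- hit[1, 1]; c0 <- hit[1, 2]; k0 <- hit[1, 3]
    cube <- A[(r0 - 1):(r0 + 1), (c0 - 1):(c0 + 1), (k0 - 1):(k0 + 1)]
    expect_equal(max(cube), cube[2, 2, 2])
    expect_equal(sum(cube == max(cube)), 1)
  }
})

test_that("detection is translation-equivariant for integer shifts", {
  img <- gauss_blobs(150, 120, cbind(c(50, 95), c(40, 80)), sigma = 2.5)
  p0 <- detect_interest_points(img)
  sh <- shift_img(img, 9, -6)
  p1 <- detect_interest_points(sh)
  expect_equal(nrow(p1), nrow(p0))
  for (i in seq_len(nrow(p0))) {
    d <- min(sqrt((p1$x - (p0$x[i] + 9))^2 + (p1$y - (p0$y[i] - 6))^2))
    expect_lt(d, 0.5)
  }
})

test_that("detected scale grows with blob size", {
  scales <- vapply(c(2.3, 2.7, 3.1, 3.5), function(sg) {
    img <- gauss_blobs(90, 90, cbind(45, 45), sigma = sg)
    pts <- detect_interest_points(img)
    expect_gt(nrow(pts), 0)
    pts$scale[1]
  }, numeric(1))
  expect_true(all(diff(scales) >= 0))
})

test_that("a gain change rescales responses without moving ranked points", {
  img <- gauss_blobs(130, 110, cbind(c(40, 85), c(40, 70)), sigma = c(2.4, 2.9))
  p1 <- detect_interest_points(img, hessian_params())
  # det(H) is quadratic in intensity: gain 2 scales responses by 4
  p2 <- detect_interest_points(0.5 + (img - 0.5) * 2,
                               hessian_params(response_threshold = 4e-4))
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(p1$x, p2$x, tolerance = 1e-6)
  expect_equal(p1$y, p2$y, tolerance = 1e-6)
  expect_equal(p2$response, 4 * p1$response, tolerance = 1e-9)
})

test_that("images smaller than the largest kernel are rejected", {
  expect_error(detect_interest_points(matrix(0.5, 20, 20)), "27")
})
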