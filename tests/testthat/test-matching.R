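# Sign-gated nearest-neighbour matching and RANSAC homography
# estimation.

# Build a descriptor tibble from a matrix of unit vectors.
desc_tbl <- function(V, sign = rep(1, nrow(V)), x = NULL, y = NULL) {
  n <- nrow(V)
  if (is.null(x)) { set.seed(n + 1); x <- runif(n, 0, 200); y <- runif(n, 0, 200) }
  out <- tibble::as_tibble(cbind(
    data.frame(x = x, y = y, scale = rep(2, n), sign = sign, norm = 1),
    stats::setNames(as.data.frame(V), paste0("v", 0:63))))
  out
}

unit_rows <- function(n, seed) {
  set.seed(seed)
  V <- matrix(rnorm(n * 64), n, 64)
  V / sqrt(rowSums(V^2))
}

test_that("a descriptor set matches itself at distance zero", {
  V <- unit_rows(12, 2)
  d <- desc_tbl(V)
  m <- match_descriptors(d, d)
  expect_equal(nrow(m), 12)
  expect_equal(m$distance, rep(0, 12), tolerance = 1e-6)
  expect_equal(m$train_index[order(m$query_index)], 1:12)
})

test_that("opposite Laplacian signs are never compared", {
  V <- unit_rows(8, 3)
  m <- match_descriptors(desc_tbl(V, sign = rep(1, 8)),
                         desc_tbl(V, sign = rep(-1, 8)))
  expect_equal(nrow(m), 0)
})

test_that("matching equals the exhaustive all-pairs oracle on random instances", {
  set.seed(17)
  for (rep in 1:100) {
    nq <- sample(1:20, 1); nt <- sample(1:30, 1)
    Q <- matrix(rnorm(nq * 64), nq, 64); Q <- Q / sqrt(rowSums(Q^2))
    T <- matrix(rnorm(nt * 64), nt, 64); T <- T / sqrt(rowSums(T^2))
    # plant near-duplicates of some queries into the train set
    for (i in seq_len(min(nq, nt))) {
      if (runif(1) < 0.5) {
        T[i, ] <- Q[i, ] + rnorm(64, 0, 0.01)
        T[i, ] <- T[i, ] / sqrt(sum(T[i, ]^2))
      }
    }
    qs <- sample(c(-1, 1), nq, replace = TRUE)
    ts <- sample(c(-1, 1), nt, replace = TRUE)
    got <- match_descriptors(desc_tbl(Q, qs), desc_tbl(T, ts))
    want <- o_match(Q, T, qs, ts)
    expect_equal(got$query_index, want$query_index)
    expect_equal(got$train_index, want$train_index)
    expect_equal(got$distance, want$distance, tolerance = 1e-12)
  }
})

test_that("empty inputs give empty matches", {
  d <- desc_tbl(unit_rows(3, 5))
  e <- d[0, ]
  expect_equal(nrow(match_descriptors(e, d)), 0)
  expect_equal(nrow(match_descriptors(d, e)), 0)
})

# Helper: matches/points for n planted correspondences under (tx, ty).
planted <- function(n, tx, ty, seed, n_out = 0) {
  set.seed(seed)
  src <- data.frame(x = runif(n, 0, 200), y = runif(n, 0, 200))
  dst <- data.frame(x = src$x + tx, y = src$y + ty)
  if (n_out > 0) {
    k <- sample(n, n_out)
    dst$x[k] <- runif(n_out, 0, 200)
    dst$y[k] <- runif(n_out, 0, 200)
    attr(dst, "outliers") <- k
  }
  list(matches = tibble::tibble(query_index = 1:n, train_index = 1:n,
                                distance = 0),
       src = src, dst = dst)
}

test_that("RANSAC recovers an exact planted translation", {
  p <- planted(10, 12, -5, seed = 7)
  h <- estimate_homography(p$matches, p$src, p$dst, match_params(rng_seed = 3))
  expect_false(is.null(h))
  expect_lt(abs(h$m[1, 3] - 12), 0.1)
  expect_lt(abs(h$m[2, 3] + 5), 0.1)
  expect_equal(h$n_inliers, 10)
})

test_that("RANSAC excludes injected outliers and still recovers the motion", {
  p <- planted(20, 12, -5, seed = 9, n_out = 6)
  h <- estimate_homography(p$matches, p$src, p$dst, match_params(rng_seed = 5))
  expect_false(is.null(h))
  expect_lt(abs(h$m[1, 3] - 12), 0.5)
  expect_lt(abs(h$m[2, 3] + 5), 0.5)
  expect_true(all(!h$inlier_mask[attr(p$dst, "outliers")]))
})

test_that("under-determined inputs give no homography", {
  p <- planted(3, 4, 4, seed = 2)
  expect_null(estimate_homography(p$matches, p$src, p$dst))
})

test_that("identical seeds give bit-identical inlier masks", {
  p <- planted(30, -8, 17, seed = 13, n_out = 8)
  h1 <- estimate_homography(p$matches, p$src, p$dst, match_params(rng_seed = 11))
  h2 <- estimate_homography(p$matches, p$src, p$dst, match_params(rng_seed = 11))
  expect_identical(h1$inlier_mask, h2$inlier_mask)
  expect_identical(h1$m, h2$m)
})

test_that("planted translations are recovered across 50 seeded trials", {
  ok <- 0
  for (seed in 1:50) {
    set.seed(seed + 400)
    t <- runif(2, -30, 30)
    n <- 20
    p <- planted(n, t[1], t[2], seed = seed + 800, n_out = 6)  # 30% outliers
    h <- estimate_homography(p$matches, p$src, p$dst,
                             match_params(rng_seed = seed))
    if (is.null(h)) next
    corners <- data.frame(x = c(0, 200, 200, 0), y = c(0, 0, 200, 200))
    got <- apply_homography(h$m, corners)
    err <- max(sqrt((got$x - corners$x - t[1])^2 +
                      (got$y - corners$y - t[2])^2))
    if (err < 0.5) ok <- ok + 1
  }
  expect_gte(ok, 48)
})

test_that("tidy and glance summarize a homography fit", {
  p <- planted(10, 3, 4, seed = 21)
  h <- estimate_homography(p$matches, p$src, p$dst)
  td <- tidy(h)
  expect_equal(nrow(td), 9)
  expect_equal(td$value[c(3, 6, 9)], c(h$m[1, 3], h$m[2, 3], 1))
  g <- glance(h)
  expect_equal(g$n_inliers, 10)
  expect_equal(g$tx, h$m[1, 3])
})
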