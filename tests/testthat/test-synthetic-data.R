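# Seeded microscopy-like fixture generator.

test_that("an empty noiseless scene yields no detections", {
  spec <- scene_spec(width = 320, height = 240, n_cells = 0,
                     background_noise_sigma = 0, clutter = 0, rng_seed = 1)
  sc <- synth_scene(spec)
  expect_equal(nrow(sc$truth$cell_centers), 0)
  expect_equal(nrow(detect_interest_points(sc$image)), 0)
})

test_that("generation is a pure function of spec and seed", {
  spec <- scene_spec(width = 320, height = 240, n_cells = 15, rng_seed = 33)
  a <- synth_scene(spec); b <- synth_scene(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$cell_centers, b$truth$cell_centers)
  c <- synth_scene(scene_spec(width = 320, height = 240, n_cells = 15,
                              rng_seed = 34))
  expect_false(identical(a$image, c$image))
})

test_that("the default culture scene's cell centres are recovered by detection", {
  spec <- scene_spec(rng_seed = 42)
  sc <- synth_scene(spec)
  pts <- detect_interest_points(sc$image)
  ctr <- sc$truth$cell_centers
  hit <- vapply(seq_len(nrow(ctr)), function(i)
    min(sqrt((pts$x - ctr$x[i])^2 + (pts$y - ctr$y[i])^2)), numeric(1))
  expect_gte(mean(hit < 2), 0.9)
  # threshold calibration: no detections away from rendered structure
  # (somata occupy a radius ~2.2 r neighbourhood around each centre)
  bg <- vapply(seq_len(nrow(pts)), function(i)
    min(sqrt((pts$x[i] - ctr$x)^2 + (pts$y[i] - ctr$y)^2)), numeric(1))
  expect_equal(sum(bg > 2.2 * max(sc$truth$cell_radii)), 0)
})

test_that("infeasible packing is rejected", {
  expect_error(synth_scene(scene_spec(width = 80, height = 80, n_cells = 50,
                                      rng_seed = 1)),
               "1000 attempts")
})

test_that("the fluorescence mask lights the fluorescent subset only", {
  spec <- scene_spec(width = 400, height = 300, n_cells = 12, rng_seed = 5)
  sc <- synth_scene(spec)
  mask <- synth_fluorescence_mask(sc$truth, spec)
  fl <- sc$truth$fluorescent_subset
  expect_gt(length(fl), 0)
  for (i in fl) {
    r0 <- round(sc$truth$cell_centers$y[i]) + 1
    c0 <- round(sc$truth$cell_centers$x[i]) + 1
    expect_gt(mask[r0, c0], 0.8)
    # peak within 1 px of the centre
    win <- mask[(r0 - 3):(r0 + 3), (c0 - 3):(c0 + 3)]
    pk <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(pk - 4)), 1)
  }
  dark <- setdiff(seq_len(12), fl)
  for (i in dark) {
    r0 <- round(sc$truth$cell_centers$y[i]) + 1
    c0 <- round(sc$truth$cell_centers$x[i]) + 1
    expect_lt(mask[r0, c0], 0.1)
  }
  # empty subset: near-black mask
  truth0 <- sc$truth; truth0$fluorescent_subset <- integer(0)
  expect_lt(max(synth_fluorescence_mask(truth0, spec)), 0.1)
})

test_that("sequences carry their homographies and match phase correlation", {
  spec <- scene_spec(width = 320, height = 240, n_cells = 15, rng_seed = 11)
  sc <- synth_scene(spec)
  seqd <- synth_sequence(sc, list(c(0, 0), c(10.5, -3.25)),
                         noise_sigma = 0.01, rng_seed = 2)
  expect_length(seqd$truth$frame_homographies, 2)
  expect_equal(seqd$truth$frame_homographies[[2]][1:2, 3], c(10.5, -3.25))
  # frame 0: only noise
  expect_lt(sd(seqd$frames[[1]] - sc$image), 0.015)
  # phase-correlation peak of frame 2 against the scene
  f1 <- sc$image - mean(sc$image)
  f2 <- seqd$frames[[2]] - mean(seqd$frames[[2]])
  xc <- Re(fft(fft(f2) * Conj(fft(f1)), inverse = TRUE))
  pk <- which(xc == max(xc), arr.ind = TRUE)[1, ]
  dx <- (pk["col"] - 1); dy <- (pk["row"] - 1)
  if (dx > 160) dx <- dx - 320
  if (dy > 120) dy <- dy - 240
  expect_lt(abs(dx - 10.5), 1)
  expect_lt(abs(dy + 3.25), 1)
  # a drift moving the ROI mostly out of view is rejected by frame
  expect_error(
    synth_sequence(sc, list(c(0, 0), c(300, 0)), roi = rect(0, 0, 100, 100)),
    "2")
})

test_that("dataset builds follow the benchmark layout and are reproducible", {
  dir <- withr::local_tempdir()
  m <- build_dataset(dir, seed = 5, sets_per_type = 1, images_per_set = 3)
  expect_equal(nrow(m), 6)
  expect_equal(sort(unique(m$type)), c("culture", "slice"))
  expect_true(all(m$roi_w[m$type == "culture"] == 140))
  expect_true(all(m$roi_h[m$type == "culture"] == 155))
  expect_true(all(m$roi_w[m$type == "slice"] == 155))
  expect_true(all(m$roi_h[m$type == "slice"] == 140))
  expect_true(all(file.exists(file.path(dir, m$path))))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  # identical seed, identical manifests and image bytes
  dir2 <- withr::local_tempdir()
  m2 <- build_dataset(dir2, seed = 5, sets_per_type = 1, images_per_set = 3)
  expect_equal(m$seed, m2$seed)
  expect_identical(readBin(file.path(dir, m$path[1]), "raw", 1e6),
                   readBin(file.path(dir2, m2$path[1]), "raw", 1e6))
  # a manifest-only build places cells (and hence ROIs) identically
  dir3 <- withr::local_tempdir()
  m3 <- build_dataset(dir3, seed = 5, sets_per_type = 1, images_per_set = 3,
                      write_images = FALSE)
  expect_equal(m[names(m) != "path"], m3[names(m3) != "path"])
  # loading restores the sweep-ready layout
  ds <- load_dataset(dir)
  expect_equal(nrow(ds), 6)
  expect_true(is.matrix(ds$image[[1]]))
})

test_that("the evaluation-set pool reproduces dataset sampling", {
  a <- synth_eval_set("culture", 2, seed = 9, width = 320, height = 240,
                      pool = 10)
  b <- synth_eval_set("culture", 2, seed = 9, width = 320, height = 240,
                      pool = 10)
  expect_identical(a$image, b$image)
  expect_true(all(a$index <= 10))
  expect_error(synth_eval_set("culture", 5, seed = 1, pool = 2), "pool")
})
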