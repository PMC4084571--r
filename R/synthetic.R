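# Seeded generator of microscopy-like images with ground truth:
# textured background, blob-like somata with DIC- or Dodt-style
# contrast, defocused clutter, paired fluorescence masks, and
# translated frame sequences with known homographies. Every generator
# is a pure function of its spec and seed.

#' Scene specification
#'
#' @param width,height Image size in pixels (default 640 x 480, the
#'   acquisition frame size the package emulates).
#' @param n_cells Number of somata.
#' @param cell_radius_range Min/max soma radius in pixels (default
#'   6-14, soma-scale blobs at 40x).
#' @param contrast_mode `"dic"` (shadow-relief along a 45 degree shear
#'   axis) or `"dodt"` (one-sided gradient contrast, lower detail).
#' @param contrast Peak soma contrast against the background on the
#'   unit intensity scale (default 0.22).
#' @param background_noise_sigma Additive Gaussian noise sigma
#'   (default 0.02).
#' @param clutter Number of defocused background blobs (out-of-focus
#'   structure in thick slices).
#' @param rng_seed Generator seed; identical spec + seed gives
#'   bit-identical images.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(width = 640L, height = 480L, n_cells = 80L,
                       cell_radius_range = c(6, 14),
                       contrast_mode = c("dic", "dodt"),
                       contrast = 0.35,
                       background_noise_sigma = 0.02,
                       clutter = 2L, rng_seed = 1L) {
  contrast_mode <- match.arg(contrast_mode)
  if (width < 1 || height < 1) abort("Scene dimensions must be positive.")
  if (n_cells < 0) abort("`n_cells` must be >= 0.")
  if (any(cell_radius_range <= 0) || diff(cell_radius_range) < 0) {
    abort("`cell_radius_range` must be positive and non-decreasing.")
  }
  assert_scalar_number(contrast, "contrast", lower = 0, upper = 1)
  assert_scalar_number(background_noise_sigma, "background_noise_sigma",
                       lower = 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_cells = as.integer(n_cells),
                 cell_radius_range = cell_radius_range,
                 contrast_mode = contrast_mode, contrast = contrast,
                 background_noise_sigma = background_noise_sigma,
                 clutter = as.integer(clutter),
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

# Add one soft-edged elliptical soma (flat-top profile exp(-rho^4)) plus
# its contrast relief to `img` in place; returns the modified matrix.
# Somata carry a compact central highlight (core_sigma > 0), the bright
# condensed center DIC/Dodt optics show for healthy cells in focus.
.render_cell <- function(img, cx, cy, r, axis_ratio, theta, amp, mode,
                         core_sigma = 0, tex_amp = 0.15) {
  ht <- nrow(img); wd <- ncol(img)
  ext <- ceiling(max(1.8 * r, 20))
  xs <- max(0, floor(cx - ext)):min(wd - 1, ceiling(cx + ext))
  ys <- max(0, floor(cy - ext)):min(ht - 1, ceiling(cy + ext))
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  rho2 <- (u / r)^2 + (v / (r * axis_ratio))^2
  # the diffuse body stays faint relative to the condensed organelles so
  # the cell's dominant scales lie inside the detector's single octave
  body <- 0.2 * amp * exp(-rho2^2)
  relief <- if (mode == "dic") {
    # antisymmetric shadow-relief along the 45-degree shear axis
    s45 <- (dx + dy) / sqrt(2)
    0.5 * 0.2 * amp * (s45 / r) * exp(-rho2^2)
  } else {
    # monotone one-sided gradient across the soma
    0.3 * 0.2 * amp * (dx / r) * exp(-rho2^2)
  }
  core <- if (core_sigma > 0) {
    1.1 * amp * exp(-(dx^2 + dy^2) / (2 * core_sigma^2))
  } else 0
  # satellite organelles: one or two compact blobs on a perinuclear
  # ring. They give every soma a unique constellation (so descriptors
  # are distinctive and the ratio test keeps matches) and are clean
  # blob keypoints themselves, like organelle highlights in DIC somata.
  # The ring radius keeps them from merging with the core at coarse
  # scales, which would destroy both space-scale maxima.
  sat <- 0
  if (core_sigma > 0) {
    n_sat <- sample(1:2, 1)
    base_ang <- runif(1, 0, 2 * pi)
    for (q in seq_len(n_sat)) {
      ang <- base_ang + (q - 1) * pi + runif(1, -0.5, 0.5)
      rad <- runif(1, 11, 14)
      sg <- runif(1, 2.5, 3.0)
      sat <- sat + amp * runif(1, 0.7, 1.0) *
        exp(-((dx - rad * cos(ang))^2 + (dy - rad * sin(ang))^2) / (2 * sg^2))
    }
  }
  # weak perinuclear speckle: descriptor-level diversity between somata;
  # amplitude kept small so its curvature never competes with the
  # core/satellite blobs in the detector
  tex <- if (core_sigma > 0 && tex_amp > 0) {
    t0 <- apply_blur(matrix(rnorm(length(dx)), nrow(dx), ncol(dx)),
                     blur_spec(4))
    donut <- 1 - exp(-(dx^2 + dy^2) / (2 * 4^2))
    tex_amp * amp * (t0 / max(stats::sd(t0), 1e-12)) * donut * exp(-rho2^2)
  } else 0
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + body + relief + core + sat + tex
  img
}

#' Generate a microscopy-like scene with ground truth
#'
#' Background is low-frequency shading plus Gaussian noise; each cell
#' is a soft-edged ellipse with DIC- or Dodt-style contrast; clutter
#' blobs are pre-blurred (sigma = 4) to mimic out-of-focus structure.
#'
#' @param spec A [scene_spec()].
#' @param render Render the pixel image (default). `render = FALSE`
#'   runs only the seeded cell-placement stage (those draws precede all
#'   rendering draws in the generator's RNG stream, so placements are
#'   bit-identical to a rendered scene's) and returns `image = NULL` —
#'   used for fast manifest-only dataset builds.
#' @return A list with `image` (matrix in `[0, 1]`) and `truth`, a list
#'   holding `cell_centers` (tibble `x`, `y`), `cell_radii`,
#'   `fluorescent_subset` (indices), `frame_homographies` (`NULL` until
#'   a sequence is generated).
#' @export
synth_scene <- function(spec = scene_spec(), render = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  wd <- spec$width; ht <- spec$height
  with_seed(spec$rng_seed, {
    if (render) {
      x01 <- matrix(rep((0:(wd - 1)) / max(1, wd - 1), each = ht), ht, wd)
      y01 <- matrix(rep((0:(ht - 1)) / max(1, ht - 1), times = wd), ht, wd)
      img <- matrix(0.42, ht, wd)
    } else {
      img <- NULL
    }
    for (i in 1:3) {  # gentle low-frequency shading
      fx <- runif(1, 0.3, 1.2); fy <- runif(1, 0.3, 1.2)
      ph <- runif(1, 0, 2 * pi)
      if (render) {
        img <- img + 0.02 * sin(2 * pi * (fx * x01 + fy * y01) + ph)
      }
    }

    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    if (spec$n_cells > 0) {
      rmin <- spec$cell_radius_range[1]; rmax <- spec$cell_radius_range[2]
      attempts <- 0L  # consecutive failures for the current cell
      while (nrow(centers) < spec$n_cells) {
        attempts <- attempts + 1L
        if (attempts > 1000L) {
          abort("Could not place all cells without overlap in 1000 attempts.")
        }
        r <- runif(1, rmin, rmax)
        margin <- 2 * r + 2
        if (wd - 2 * margin <= 0 || ht - 2 * margin <= 0) {
          abort("Could not place all cells without overlap in 1000 attempts.")
        }
        cx <- runif(1, margin, wd - 1 - margin)
        cy <- runif(1, margin, ht - 1 - margin)
        if (nrow(centers)) {
          d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
          if (any(d < radii + r + 16)) next
        }
        centers <- rbind(centers, c(cx, cy))
        radii <- c(radii, r)
        attempts <- 0L
      }
      if (render) for (i in seq_len(spec$n_cells)) {
        amp <- spec$contrast * runif(1, 0.8, 1.2)
        # dark (phase-reversed) somata appear at reduced contrast so the
        # intensity range stays clear of the black clip point
        if (runif(1) >= 0.75) amp <- -0.7 * amp
        img <- .render_cell(img, centers[i, 1], centers[i, 2], radii[i],
                            axis_ratio = runif(1, 0.8, 1),
                            theta = runif(1, 0, pi), amp = amp,
                            mode = spec$contrast_mode,
                            core_sigma = runif(1, 2.4, 2.9))
      }
    }

    if (render && spec$clutter > 0) {
      clut <- matrix(0, ht, wd)
      for (i in seq_len(spec$clutter)) {
        cx <- runif(1, 0, wd - 1); cy <- runif(1, 0, ht - 1)
        r <- runif(1, 8, 25)
        amp <- runif(1, 0.03, 0.08) * sample(c(-1, 1), 1)
        clut <- .render_cell(clut, cx, cy, r, 1, 0, amp, "dodt")
      }
      img <- img + apply_blur(clut, blur_spec(8))  # sigma = 4 defocus
    }

    if (render && spec$background_noise_sigma > 0) {
      img <- img + matrix(rnorm(ht * wd, 0, spec$background_noise_sigma),
                          ht, wd)
    }
    if (render) img <- pmax(pmin(img, 1), 0)

    fl <- if (render && spec$n_cells > 0) {
      sel <- which(runif(spec$n_cells) < 0.5)
      if (!length(sel)) sel <- 1L
      sel
    } else integer(0)

    list(image = img,
         truth = list(
           cell_centers = tibble(x = centers[, 1], y = centers[, 2]),
           cell_radii = radii,
           fluorescent_subset = fl,
           frame_homographies = NULL))
  })
}

#' Fluorescence mask for a generated scene
#'
#' Dark background (0.02) with bright Gaussian spots (peak 0.9) at the
#' fluorescent subset of cell centers, co-registered with the
#' transmission scene.
#'
#' @param scene_truth The `truth` component of [synth_scene()] output.
#' @param spec The [scene_spec()] used for the scene.
#' @return An image matrix.
#' @export
synth_fluorescence_mask <- function(scene_truth, spec) {
  stopifnot(inherits(spec, "scene_spec"))
  ht <- spec$height; wd <- spec$width
  img <- matrix(0.02, ht, wd)
  for (i in scene_truth$fluorescent_subset) {
    cx <- scene_truth$cell_centers$x[i]
    cy <- scene_truth$cell_centers$y[i]
    r <- scene_truth$cell_radii[i]
    sg <- 0.6 * r
    ext <- ceiling(3 * sg)
    xs <- max(0, floor(cx - ext)):min(wd - 1, ceiling(cx + ext))
    ys <- max(0, floor(cy - ext)):min(ht - 1, ceiling(cy + ext))
    dx <- outer(rep(1, length(ys)), xs - cx)
    dy <- outer(ys - cy, rep(1, length(xs)))
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] +
      0.9 * exp(-(dx^2 + dy^2) / (2 * sg^2))
  }
  pmax(pmin(img, 1), 0)
}

#' Generate a translated frame sequence with known homographies
#'
#' Each frame is the scene resampled under the pure-translation
#' homography of its drift (bilinear, sub-pixel drifts allowed,
#' replicate-edge sampling) plus fresh additive Gaussian noise.
#'
#' @param scene A scene list from [synth_scene()] (fields `image`,
#'   `truth`).
#' @param drifts List (or 2-column matrix) of `(tx, ty)` translations,
#'   one per frame.
#' @param noise_sigma Per-frame additive noise sigma.
#' @param roi Optional [rect()]; each drift must keep at least 50% of
#'   the ROI in view (the full image when `roi` is `NULL`).
#' @param rng_seed Noise seed.
#' @return A list with `frames` (list of matrices) and `truth` (the
#'   scene truth with `frame_homographies` filled in).
#' @export
synth_sequence <- function(scene, drifts, noise_sigma = 0.02, roi = NULL,
                           rng_seed = 1L) {
  img <- scene$image
  ht <- nrow(img); wd <- ncol(img)
  if (is.matrix(drifts)) drifts <- asplit(drifts, 1)
  box <- if (is.null(roi)) list(x = 0, y = 0, w = wd, h = ht) else
    list(x = roi$x, y = roi$y, w = roi$w, h = roi$h)
  hs <- vector("list", length(drifts))
  for (i in seq_along(drifts)) {
    t <- drifts[[i]]
    ox <- max(0, min(box$x + t[1] + box$w, wd) - max(box$x + t[1], 0))
    oy <- max(0, min(box$y + t[2] + box$h, ht) - max(box$y + t[2], 0))
    if (ox * oy < 0.5 * box$w * box$h) {
      abort(sprintf("Drift %d (%.1f, %.1f) leaves under 50%% of the ROI in view.",
                    i, t[1], t[2]))
    }
    hs[[i]] <- matrix(c(1, 0, t[1], 0, 1, t[2], 0, 0, 1), 3, 3, byrow = TRUE)
  }
  px <- rep(0:(wd - 1L), each = ht)
  py <- rep(0:(ht - 1L), times = wd)
  frames <- with_seed(rng_seed, lapply(seq_along(drifts), function(i) {
    t <- drifts[[i]]
    f <- matrix(.bilinear_sample(img, px - t[1], py - t[2],
                                 outside = "clamp"), ht, wd)
    if (noise_sigma > 0) {
      f <- f + matrix(rnorm(ht * wd, 0, noise_sigma), ht, wd)
    }
    pmax(pmin(f, 1), 0)
  }))
  truth <- scene$truth
  truth$frame_homographies <- hs
  list(frames = frames, truth = truth)
}

# ROI of size (w x h) centered on the densest cell cluster: among
# candidate centres at each cell, pick the one whose window contains
# the most cells (ties -> first), clamped inside the image.
.roi_densest <- function(truth, w, h, wd, ht) {
  ctr <- truth$cell_centers
  if (nrow(ctr) == 0L) {
    return(rect(floor((wd - w) / 2), floor((ht - h) / 2), w, h))
  }
  best <- 1L; best_n <- -1L
  for (i in seq_len(nrow(ctr))) {
    x0 <- min(max(round(ctr$x[i] - w / 2), 0), wd - w)
    y0 <- min(max(round(ctr$y[i] - h / 2), 0), ht - h)
    n_in <- sum(ctr$x >= x0 & ctr$x < x0 + w & ctr$y >= y0 & ctr$y < y0 + h)
    if (n_in > best_n) { best_n <- n_in; best <- i }
  }
  x0 <- min(max(round(ctr$x[best] - w / 2), 0), wd - w)
  y0 <- min(max(round(ctr$y[best] - h / 2), 0), ht - h)
  rect(x0, y0, w, h)
}

# Scene spec templates for the two image types the dataset emulates.
# Cell counts scale with the field-of-view area (the defaults are per
# 640 x 480 frame).
.type_spec <- function(type, seed, width = 640L, height = 480L) {
  area <- (width * height) / (640 * 480)
  if (type == "culture") {
    scene_spec(width = width, height = height,
               n_cells = max(1L, round(80L * area)),
               contrast_mode = "dic", contrast = 0.35,
               background_noise_sigma = 0.02,
               clutter = max(1L, round(2L * area)),
               rng_seed = seed)
  } else {
    scene_spec(width = width, height = height,
               n_cells = max(1L, round(70L * area)),
               contrast_mode = "dodt", contrast = 0.25,
               background_noise_sigma = 0.025,
               clutter = max(1L, round(12L * area)),
               rng_seed = seed)
  }
}

# ROI sizes per image type (width x height).
.type_roi <- function(type) {
  if (type == "culture") c(140L, 155L) else c(155L, 140L)
}

#' Generate an in-memory evaluation set
#'
#' Convenience wrapper producing `n` images of one type together with
#' their ROIs, in the tibble layout [run_sweep()] consumes.
#'
#' @param type `"culture"` or `"slice"`.
#' @param n Number of images to generate.
#' @param seed Seed; image `i` uses an independent sub-seed.
#' @param width,height Image size.
#' @param pool Size of the seeded image pool that `n` images are drawn
#'   from without replacement (default `pool = n`, no sampling). With
#'   `pool = 360, n = 36` this reproduces a 10% random sample of one
#'   image type of the benchmark dataset without generating the other
#'   90%.
#' @return A tibble with columns `image` (list of matrices), `type`,
#'   `index` (position in the pool), `roi_x`, `roi_y`, `roi_w`,
#'   `roi_h`.
#' @export
synth_eval_set <- function(type = c("culture", "slice"), n, seed = 1L,
                           width = 640L, height = 480L, pool = n) {
  type <- match.arg(type)
  if (pool < n) abort("`pool` must be at least `n`.")
  picked <- with_seed(seed, {
    pool_seeds <- sample.int(.Machine$integer.max, pool)
    idx <- if (pool > n) sort(sample.int(pool, n)) else seq_len(n)
    list(seeds = pool_seeds[idx], idx = idx)
  })
  seeds <- picked$seeds
  roi_wh <- .type_roi(type)
  rows <- lapply(seq_len(n), function(i) {
    sc <- synth_scene(.type_spec(type, seeds[i], width, height))
    roi <- .roi_densest(sc$truth, min(roi_wh[1], width),
                        min(roi_wh[2], height), width, height)
    tibble(image = list(sc$image), type = type, index = picked$idx[i],
           roi_x = roi$x, roi_y = roi$y, roi_w = roi$w, roi_h = roi$h)
  })
  dplyr::bind_rows(rows)
}

#' Build the synthetic benchmark dataset on disk
#'
#' Eight sets of 90 images (four culture-like, four slice-like; 720
#' images in total) at 640 x 480, with per-image ROI records of
#' 140 x 155 (culture) and 155 x 140 (slice) centered on the densest
#' cell cluster. Slice-like images carry heavier defocused clutter and
#' lower contrast. A manifest CSV lists every image.
#'
#' @param out_dir Output directory (created if missing); layout
#'   `<type>/set<k>/img<j>.png`.
#' @param seed Master seed; every image derives its own sub-seed.
#' @param sets_per_type,images_per_set Dataset shape (defaults 4 and
#'   90).
#' @param write_images Write the PNGs (default `TRUE`); `FALSE`
#'   computes the manifest only.
#' @return The manifest tibble (`path`, `type`, `set`, `index`,
#'   `roi_x`, `roi_y`, `roi_w`, `roi_h`, `seed`), invisibly written to
#'   `manifest.csv` in `out_dir`.
#' @export
build_dataset <- function(out_dir, seed = 1L, sets_per_type = 4L,
                          images_per_set = 90L, write_images = TRUE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory '%s'.", out_dir))
  }
  if (file.access(out_dir, 2) != 0) {
    abort(sprintf("Output directory '%s' is not writable.", out_dir))
  }
  types <- c("culture", "slice")
  total <- length(types) * sets_per_type * images_per_set
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, total))
  rows <- vector("list", total)
  i <- 0L
  for (type in types) {
    roi_wh <- .type_roi(type)
    for (k in seq_len(sets_per_type)) {
      dir.create(file.path(out_dir, type, paste0("set", k)),
                 recursive = TRUE, showWarnings = FALSE)
      for (j in seq_len(images_per_set)) {
        i <- i + 1L
        sc <- synth_scene(.type_spec(type, seeds[i]), render = write_images)
        roi <- .roi_densest(sc$truth, roi_wh[1], roi_wh[2], 640L, 480L)
        rel <- file.path(type, paste0("set", k), sprintf("img%02d.png", j))
        if (write_images) {
          write_image(sc$image, file.path(out_dir, rel))
        }
        rows[[i]] <- tibble(path = rel, type = type, set = k, index = j,
                            roi_x = roi$x, roi_y = roi$y,
                            roi_w = roi$w, roi_h = roi$h,
                            seed = seeds[i])
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  manifest
}

#' Load a built dataset into memory
#'
#' @param dir Directory produced by [build_dataset()].
#' @return A tibble in the [run_sweep()] layout (list-column `image`
#'   plus the manifest columns).
#' @export
load_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) abort(sprintf("No manifest.csv under '%s'.", dir))
  manifest <- as_tibble(read.csv(mf, stringsAsFactors = FALSE))
  manifest$image <- lapply(manifest$path, function(p)
    read_image(file.path(dir, p)))
  manifest
}
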