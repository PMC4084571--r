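# Robustness study: sweep degradation levels over a sampled image set,
# count good matches of the clean ROI template against the degraded
# frame, and summarize per level with means and 95% confidence
# intervals.

#' Sweep configuration
#'
#' @param mode `"blur"` (Gaussian defocus levels) or `"brightness"`
#'   (additive offset levels).
#' @param levels Ordered integer levels; defaults to 1..13 for blur and
#'   1..100 for brightness.
#' @param sample_fraction Fraction of the dataset drawn without
#'   replacement (default 0.10, the study's sampling rate); at 1 the
#'   whole set is used and the seed is irrelevant.
#' @param rng_seed Sampling seed.
#' @param ci Confidence-interval method: `"normal"`
#'   (`mean +/- 1.96 * sd / sqrt(n)`) or `"bootstrap"` (seeded
#'   percentile, `n_boot` resamples).
#' @param n_boot Bootstrap resamples (default 1000).
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(mode = c("blur", "brightness"), levels = NULL,
                         sample_fraction = 0.10, rng_seed = 1L,
                         ci = c("normal", "bootstrap"), n_boot = 1000L) {
  mode <- match.arg(mode)
  ci <- match.arg(ci)
  if (is.null(levels)) levels <- if (mode == "blur") 1:13 else 1:100
  levels <- as.integer(levels)
  if (!length(levels) || any(levels < 0)) abort("`levels` must be non-negative integers.")
  assert_scalar_number(sample_fraction, "sample_fraction")
  if (sample_fraction <= 0 || sample_fraction > 1) {
    abort("`sample_fraction` must satisfy 0 < fraction <= 1.")
  }
  structure(list(mode = mode, levels = levels,
                 sample_fraction = sample_fraction,
                 rng_seed = as.integer(rng_seed), ci = ci,
                 n_boot = as.integer(n_boot)),
            class = "sweep_config")
}

# Good-match count of a clean ROI template against one (possibly
# degraded) frame.
count_good_matches <- function(template_desc, frame, hessian, matcher,
                               descriptor) {
  pts <- detect_interest_points(frame, hessian)
  desc <- describe_points(frame, pts, descriptor)
  nrow(match_descriptors(template_desc, desc, matcher))
}

# Clean-ROI template descriptors for one dataset row.
roi_template_descriptors <- function(img, roi, hessian, descriptor) {
  patch <- img[(roi$y + 1):(roi$y + roi$h),
               (roi$x + 1):(roi$x + roi$w), drop = FALSE]
  pts <- detect_interest_points(patch, hessian)
  pts$x <- pts$x + roi$x
  pts$y <- pts$y + roi$y
  describe_points(img, pts, descriptor)
}

#' Run a degradation sweep
#'
#' Samples `ceil(fraction * N)` images without replacement (seeded),
#' then for every sampled image and level: degrades the full image,
#' detects and describes both the undegraded ROI template and the
#' degraded image, and counts good matches. Per level the mean count
#' and its 95% CI are reported.
#'
#' @param dataset A tibble with a list-column `image` (unit-range image
#'   matrices) and ROI columns `roi_x`, `roi_y`, `roi_w`, `roi_h`
#'   (0-based), e.g. from [load_dataset()] or [synth_eval_set()].
#' @param cfg A [sweep_config()].
#' @param hessian,matcher,descriptor Parameter objects.
#' @return A tibble of class `eval_curve` with columns `level`, `n`,
#'   `mean_good`, `ci_lower`, `ci_upper`; the per-image counts are
#'   attached as attribute `counts` (levels x images matrix).
#' @export
run_sweep <- function(dataset, cfg = sweep_config(),
                      hessian = hessian_params(),
                      matcher = match_params(),
                      descriptor = descriptor_params()) {
  stopifnot(inherits(cfg, "sweep_config"))
  n_all <- nrow(dataset)
  if (is.null(n_all) || n_all == 0L) abort("`dataset` is empty.")
  n_s <- ceiling(cfg$sample_fraction * n_all)
  idx <- if (n_s >= n_all) seq_len(n_all) else
    with_seed(cfg$rng_seed, sort(sample.int(n_all, n_s)))

  counts <- matrix(NA_real_, length(cfg$levels), length(idx))
  for (j in seq_along(idx)) {
    row <- dataset[idx[j], ]
    img <- row$image[[1]]
    roi <- list(x = row$roi_x, y = row$roi_y, w = row$roi_w, h = row$roi_h)
    tmpl <- roi_template_descriptors(img, roi, hessian, descriptor)
    for (k in seq_along(cfg$levels)) {
      lev <- cfg$levels[k]
      deg <- if (cfg$mode == "blur") {
        apply_blur(img, blur_spec(lev))
      } else {
        apply_photometric(img, photometric_spec(level = lev))
      }
      counts[k, j] <- count_good_matches(tmpl, deg, hessian, matcher,
                                         descriptor)
    }
  }

  n <- ncol(counts)
  mean_good <- rowMeans(counts)
  if (cfg$ci == "normal") {
    se <- apply(counts, 1, sd) / sqrt(n)
    lo <- mean_good - 1.96 * se
    hi <- mean_good + 1.96 * se
  } else {
    qs <- with_seed(cfg$rng_seed, t(apply(counts, 1, function(x) {
      bm <- replicate(cfg$n_boot, mean(sample(x, length(x), replace = TRUE)))
      quantile(bm, c(0.025, 0.975), names = FALSE)
    })))
    lo <- qs[, 1]; hi <- qs[, 2]
  }
  out <- tibble(level = cfg$levels, n = n, mean_good = mean_good,
                ci_lower = lo, ci_upper = hi)
  attr(out, "counts") <- counts
  attr(out, "mode") <- cfg$mode
  class(out) <- c("eval_curve", class(out))
  out
}

#' Five-number summaries of good-match counts per condition
#'
#' Quartiles are type-7 sample quantiles; whiskers follow the
#' 1.5 * IQR rule (most extreme observations within the fences), and
#' observations beyond the fences are listed as outliers.
#'
#' @param per_image_counts A named list of numeric count vectors, one
#'   per condition.
#' @return A tibble with columns `condition`, `n`, `median`, `q1`,
#'   `q3`, `lo_whisker`, `hi_whisker`, `n_outliers`, and a list-column
#'   `outliers`.
#' @export
summarize_matches <- function(per_image_counts) {
  if (!length(per_image_counts)) abort("At least one condition is required.")
  if (is.null(names(per_image_counts))) {
    names(per_image_counts) <- paste0("condition", seq_along(per_image_counts))
  }
  purrr::imap_dfr(per_image_counts, function(x, nm) {
    if (!length(x)) abort(sprintf("Condition '%s' has no counts.", nm))
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo_f <- q[1] - 1.5 * iqr; hi_f <- q[3] + 1.5 * iqr
    inside <- x >= lo_f & x <= hi_f
    tibble(condition = nm, n = length(x), median = q[2], q1 = q[1],
           q3 = q[3],
           lo_whisker = min(x[inside]), hi_whisker = max(x[inside]),
           n_outliers = sum(!inside), outliers = list(sort(x[!inside])))
  })
}

#' Plot an evaluation curve
#'
#' Mean good matches (solid line) with the 95% CI as dashed lines,
#' the layout of the robustness figures.
#'
#' @param object An `eval_curve` tibble from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_curve
#' @export
autoplot.eval_curve <- function(object, ...) {
  mode <- attr(object, "mode")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$level)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_good), colour = "black") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_lower), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_upper), linetype = "dashed") +
    ggplot2::labs(
      x = if (identical(mode, "blur")) "Blur level" else "Brightness level",
      y = "Mean good matches") +
    ggplot2::theme_classic()
}
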