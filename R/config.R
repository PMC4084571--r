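# JSON run configuration with strict unknown-key rejection — a typo in
# a detector threshold silently changes every downstream result, so
# unknown keys are an error, not a warning.

#' Default run configuration
#'
#' @return A nested list of class `run_config` with all documented
#'   defaults (detector kernels 9/15/21/27 and weight 0.9, descriptor
#'   window 20s/Haar 2s/sigma 3.3s, matcher ratio 0.7 and RANSAC
#'   threshold 3 px, blend alpha 0.5, degradation maps sigma = 0.5 *
#'   level and offset = level/255, sweep fraction 0.10).
#' @export
default_config <- function() {
  structure(list(
    detector = list(kernel_sizes = c(9L, 15L, 21L, 27L), weight_w = 0.9,
                    response_threshold = 1e-4),
    descriptor = list(window_factor = 20, haar_factor = 2,
                      sigma_factor = 3.3),
    matcher = list(ratio = 0.7, single_candidate_max = 0.25,
                   ransac_threshold = 3.0, ransac_max_iter = 2000L,
                   rng_seed = 1L),
    blend = list(alpha = 0.5),
    degradation = list(sigma_per_level = 0.5, offset_per_level = 1 / 255),
    sweep = list(sample_fraction = 0.10, mode = "blur", levels = NULL,
                 rng_seed = 1L, ci = "normal", n_boot = 1000L),
    tracking = list(min_matches = 4L),
    seed = 1L,
    verbosity = 1L
  ), class = "run_config")
}

# Merge `user` into `base`, rejecting keys absent from `base`; `path`
# accumulates the dotted key path for error messages.
merge_config <- function(base, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base)) {
      abort(sprintf("Unknown configuration key: `%s`.", full))
    }
    if (is.list(base[[key]]) && !is.null(base[[key]])) {
      if (!is.list(user[[key]])) {
        abort(sprintf("Configuration key `%s` must be a section.", full))
      }
      base[[key]] <- merge_config(base[[key]], user[[key]], c(path, key))
    } else {
      # single-bracket assignment keeps keys whose new value is NULL
      base[key] <- list(user[[key]])
    }
  }
  base
}

# Build the parameter objects, turning constructor errors into
# key-path diagnostics. Returns the config invisibly when valid.
validate_config <- function(cfg) {
  try_section <- function(section, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Invalid configuration under `%s`: %s",
                    section, conditionMessage(e)))
    })
  }
  try_section("detector", cfg_hessian(cfg))
  try_section("descriptor", cfg_descriptor(cfg))
  try_section("matcher", cfg_matcher(cfg))
  try_section("blend", blend_spec(cfg$blend$alpha))
  try_section("degradation", {
    assert_scalar_number(cfg$degradation$sigma_per_level,
                         "degradation.sigma_per_level")
    assert_scalar_number(cfg$degradation$offset_per_level,
                         "degradation.offset_per_level")
    if (cfg$degradation$sigma_per_level <= 0) {
      abort("`degradation.sigma_per_level` must be > 0.")
    }
  })
  try_section("sweep", sweep_config(
    mode = cfg$sweep$mode, levels = cfg$sweep$levels,
    sample_fraction = cfg$sweep$sample_fraction,
    rng_seed = cfg$sweep$rng_seed, ci = cfg$sweep$ci,
    n_boot = cfg$sweep$n_boot))
  try_section("tracking", {
    if (cfg$tracking$min_matches < 1) {
      abort("`tracking.min_matches` must be >= 1.")
    }
  })
  invisible(cfg)
}

#' Load a run configuration
#'
#' Missing keys take the documented defaults; unknown keys are rejected
#' with their dotted path; out-of-range values are rejected naming the
#' offending key.
#'
#' @param path Path to a JSON configuration file, or `NULL` for pure
#'   defaults.
#' @param verbose Echo the effective configuration to the log.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path = NULL, verbose = FALSE) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- tryCatch(
      jsonlite::read_json(path, simplifyVector = TRUE),
      error = function(e) abort(sprintf("Malformed JSON in '%s': %s",
                                        path, conditionMessage(e))))
    cfg2 <- merge_config(unclass(cfg), user)
    cfg <- structure(cfg2, class = "run_config")
  }
  validate_config(cfg)
  nt_log("config_loaded", hash = config_hash(cfg), verbose = verbose)
  cfg
}

#' Save a run configuration as JSON
#'
#' @param cfg A `run_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

# Short content hash of the effective configuration, for logging.
config_hash <- function(cfg) {
  substr(rlang::hash(unclass(cfg)), 1, 12)
}

# Parameter objects from a config.
cfg_hessian <- function(cfg) {
  hessian_params(cfg$detector$kernel_sizes, cfg$detector$weight_w,
                 cfg$detector$response_threshold)
}
cfg_descriptor <- function(cfg) {
  descriptor_params(cfg$descriptor$window_factor, cfg$descriptor$haar_factor,
                    cfg$descriptor$sigma_factor)
}
cfg_matcher <- function(cfg) {
  match_params(cfg$matcher$ratio, cfg$matcher$single_candidate_max,
               cfg$matcher$ransac_threshold, cfg$matcher$ransac_max_iter,
               cfg$matcher$rng_seed)
}
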