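# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. Used by every seeded operation (RANSAC, generators, sweeps).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Half-up rounding (round() in R rounds half to even, which would make the
# descriptor sampling grid depend on parity; half-up is deterministic).
round_half_up <- function(x) floor(x + 0.5)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

# One structured log line to stderr: "<ts> <level> <event> key=value ..."
nt_log <- function(event, ..., level = "INFO", verbose = TRUE) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  kv <- list(...)
  tail <- if (length(kv)) {
    paste(sprintf("%s=%s", names(kv), vapply(kv, function(v)
      paste(format(v), collapse = ","), character(1))), collapse = " ")
  } else ""
  message(sprintf("%s %s %s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level, event, tail))
  invisible(NULL)
}
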