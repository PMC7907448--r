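# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals (e.g. the
#' tie-breaking jitter of the MI estimator) never perturb a user's random
#' stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic child seed derivation: one master seed fans out to per-stage
# streams. Kept inside 32-bit signed range.
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 104729 * as.double(offset)) %% 2147483629)
}

# order() with C-locale (radix) collation so gene-id tie-breaks are
# platform-independent.
order_radix <- function(...) order(..., method = "radix")

stop_ft <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
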