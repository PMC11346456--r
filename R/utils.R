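# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user
# simulations.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Scalar checks used by the fitting functions; all stop() with the offending
# argument named so pipeline errors are actionable.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, allow_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (integer && x != trunc(x)) {
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  }
  ok_low <- if (allow_lower) x >= lower else x > lower
  if (!ok_low || x > upper) {
    stop(sprintf("`%s` = %g outside its allowed range %s%g, %g]", name, x,
                 if (allow_lower) "[" else "(", lower, upper), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
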