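# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state so
# package functions never disturb the global random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict && x <= min) {
    stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  }
  if (!strict && x < min) {
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  }
  invisible(x)
}

# Condition-number guard used before any 2x2 solve.
check_nonsingular <- function(m, what, tol = 1e12) {
  k <- kappa(m, exact = TRUE)
  if (!is.finite(k) || k > tol) {
    stop(sprintf("%s is singular or near-singular (condition number %.3g)",
                 what, k), call. = FALSE)
  }
  invisible(k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
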