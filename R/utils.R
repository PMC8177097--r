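# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Scalar, finite, non-negative check used by concentration arguments.
check_conc <- function(x, name, allow_zero = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  lo <- if (allow_zero) 0 else .Machine$double.eps
  if (any(x < lo))
    stop(sprintf("'%s' must be %s", name,
                 if (allow_zero) ">= 0" else "> 0"), call. = FALSE)
  invisible(x)
}

# Evaluate a zero-intercept polynomial sum(coef[k] * x^k).
polyval0 <- function(coefficients, x) {
  out <- numeric(length(x))
  for (k in seq_along(coefficients)) out <- out + coefficients[k] * x^k
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
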