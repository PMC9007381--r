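# Internal helpers shared across modules.

# Run `expr` under `seed` if one is given, restoring the caller's RNG state
# afterwards; with seed = NULL the current RNG stream is used as-is.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_invalid("`%s` = %g is outside the admissible range %s%g, %g%s",
                 name, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]")
  }
  invisible(x)
}

check_count_vector <- function(x, name, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop_invalid("`%s` must be a non-empty numeric vector", name)
  }
  if (anyNA(x) || any(!is.finite(x))) stop_invalid("`%s` contains non-finite values", name)
  if (any(x < 0)) stop_invalid("`%s` contains negative values", name)
  if (any(x != round(x))) stop_invalid("`%s` contains non-integer counts", name)
  if (!allow_zero && sum(x) == 0) stop_invalid("`%s` sums to zero", name)
  invisible(x)
}

# 0 * log(0) := 0, the usual entropy convention.
xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  out
}
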