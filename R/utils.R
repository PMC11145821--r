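# Internal helpers shared across modules.

# Derive `n` reproducible child seeds from one master seed without
# disturbing the caller's RNG state. Child i depends only on (seed, i),
# so replications can be regenerated independently and in any order.
split_seed <- function(seed, n, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  withr::with_seed(as.integer(seed) + 1000003L * as.integer(stream), {
    sample.int(.Machine$integer.max - 1L, n)
  })
}

# Evaluate `expr` under a fixed seed when one is given, restoring the
# RNG state afterwards; with seed = NULL the global stream is used.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 closed_lower = TRUE, closed_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (closed_lower) x >= lower else x > lower) &&
    (if (closed_upper) x <= upper else x < upper)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number in %s%s, %s%s",
                  name,
                  if (closed_lower) "[" else "(", format(lower),
                  format(upper), if (closed_upper) "]" else ")"))
  }
  invisible(x)
}

assert_binary <- function(x, name = "X", require_both = TRUE) {
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    abort(sprintf("`%s` must be a binary 0/1 vector without missing values (observed values: %s)",
                  name, paste(utils::head(sort(unique(x)), 5), collapse = ", ")))
  }
  if (require_both && length(unique(x)) < 2) {
    abort(sprintf("`%s` must contain both exposure groups", name))
  }
  invisible(x)
}
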