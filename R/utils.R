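# Internal helpers shared across modules.

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

# clip rates away from 0/1 before logit transforms
clip_rate <- function(p, eps = 0.001) pmin(pmax(p, eps), 1 - eps)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_invalid(name, " must be numeric and non-missing")
  }
  lo <- if (allow_zero) 0 else .Machine$double.xmin
  if (any(x < lo) || any(x > 1) || (!allow_one && any(x == 1))) {
    stop_invalid(name, " must be a probability in ",
                 if (allow_zero) "[0," else "(0,", if (allow_one) "1]" else "1)")
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    stop_invalid(name, " must be positive")
  }
  invisible(x)
}

# derive a reproducible 32-bit sub-seed from a master seed and an index
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  eval.parent(substitute(expr))
}
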