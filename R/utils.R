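# Internal helpers shared across modules.

# Typed validation error so loaders/tests can distinguish bad input from bugs.
bp_stop <- function(msg, class = "bp_validation_error", ...) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_prob <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    bp_stop(sprintf("'%s' must be numeric with no missing values", name))
  }
  lo <- if (allow_zero) 0 else .Machine$double.eps
  hi <- if (allow_one) 1 else 1 - .Machine$double.eps
  if (any(x < lo | x > hi)) {
    bp_stop(sprintf("'%s' must lie in [%s, %s]", name,
                    if (allow_zero) "0" else ">0", if (allow_one) "1" else "<1"))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    bp_stop(sprintf("'%s' must be non-negative with no missing values", name))
  }
  invisible(x)
}

# Recycle a scalar to length n, or check length.
recycle_to <- function(x, n, name) {
  if (length(x) == 1L) return(rep(as.numeric(x), n))
  if (length(x) != n) {
    bp_stop(sprintf("'%s' must have length 1 or %d (got %d)", name, n, length(x)))
  }
  as.numeric(x)
}

# Stable small hash of an R object (config provenance in output files).
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  raw <- utf8ToInt(txt)
  h <- 5381
  for (v in raw) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
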