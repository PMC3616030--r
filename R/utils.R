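# internal validation helpers

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) != 1L) || anyNA(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name),
         call. = FALSE)
  }
  if (any(x < lower) || any(x > upper)) {
    stop(sprintf("`%s` must be in [%s, %s] (got %s)", name,
                 format(lower), format(upper), format(x[1])), call. = FALSE)
  }
  invisible(x)
}

check_vector <- function(x, name, len = NULL, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("`%s` must be a numeric vector without missing values", name),
         call. = FALSE)
  }
  if (!is.null(len) && length(x) != len) {
    stop(sprintf("`%s` must have length %d (got %d)", name, len, length(x)),
         call. = FALSE)
  }
  if (any(x < lower) || any(x > upper)) {
    stop(sprintf("`%s` has entries outside [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
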