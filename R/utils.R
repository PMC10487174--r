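# Internal condition helpers. Validation errors (malformed input, schema
# violations) and fitting errors (model non-convergence, separation) carry
# distinct classes so callers -- in particular the CLI -- can map them to
# distinct exit codes.

abort_validation <- function(message, ...) {
  rlang::abort(message, class = "hi_validation_error", ...)
}

abort_fit <- function(message, ...) {
  rlang::abort(message, class = "hi_fit_error", ...)
}

warn_hi <- function(message, ...) {
  rlang::warn(message, class = "hi_warning", ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort_validation(sprintf(
      "`%s` must be a single finite number in [%s, %s], got %s",
      name, format(lower), format(upper), paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort_validation(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
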