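# internal validation helpers

stop_validation <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_numeric_finite <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop_validation(field, "must be finite numeric with no missing values")
  invisible(x)
}

assert_nonneg <- function(x, field) {
  assert_numeric_finite(x, field)
  if (any(x < 0)) stop_validation(field, "must be non-negative")
  invisible(x)
}

assert_positive <- function(x, field) {
  assert_numeric_finite(x, field)
  if (any(x <= 0)) stop_validation(field, "must be strictly positive")
  invisible(x)
}

assert_pct <- function(x, field) {
  assert_numeric_finite(x, field)
  if (any(x < 0 | x > 100)) stop_validation(field, "must lie in [0, 100]")
  invisible(x)
}

assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop_validation(name, paste0("missing column(s): ",
                                 paste(missing, collapse = ", ")))
  invisible(df)
}
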