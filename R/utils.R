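clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_config("%s is missing required column(s): %s",
                what, paste(missing, collapse = ", "))
  }
  invisible(df)
}
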