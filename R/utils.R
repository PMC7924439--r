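`%||%` <- function(x, y) if (is.null(x)) y else x

# locale-independent (byte order) sort permutation, for byte-stable output
radix_order <- function(...) order(..., method = "radix")

tg_log <- function(level, ..., threshold = getOption("taxograph.log_level", "info")) {
  levels <- c(quiet = 0L, info = 1L, debug = 2L)
  if (levels[[level %||% "info"]] <= levels[[threshold]]) {
    message("[taxograph] ", ...)
  }
  invisible(NULL)
}
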