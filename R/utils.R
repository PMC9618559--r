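# Internal helpers: structured errors, logging, seed sub-streams.

stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("motistate_validation_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("motistate_io_error", "error")))
}

ms_log <- function(..., level = "info") {
  message(sprintf("[motistate:%s] %s", level, paste0(...)))
}

# Deterministic sub-seed per pipeline stage so that stages can be re-run
# standalone with the same draws. Kept below 2^31.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 104729 * offset) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x > 0 && x == round(x)
}

assert_count <- function(x, name) {
  if (!is_count(x)) stop_validation("'", name, "' must be a positive integer")
  invisible(as.integer(x))
}

assert_prob <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop_validation("'", name, "' must be a probability in [0, 1]")
  invisible(as.numeric(x))
}
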