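# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

# stop() with a consistent prefix so pipeline stage failures are attributable
abort_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}

# Cheap numeric fingerprint used in run reports to make reruns comparable
# without a cryptographic digest dependency.
num_fingerprint <- function(x) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) return(0)
  round(sum(x) + stats::sd(x) * length(x), 6)
}

# seed derivation: keep derived seeds positive and below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
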