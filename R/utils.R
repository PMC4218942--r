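#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

abort_validation <- function(...) {
  stop(structure(class = c("devsource_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

abort_format <- function(...) {
  stop(structure(class = c("devsource_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' A single pipeline seed fans out to per-stage, per-subject substreams by
#' stable hashing of the (seed, label) pair, so cohorts are reproducible
#' subject-wise and stages are decoupled. The result is kept below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param ... labels (stage name, subject index, ...) identifying the stream.
#' @return a single integer usable with [set.seed()].
#' @export
substream_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(max(h, 1L))
}

# z-score with the convention that a zero-variance vector maps to all zeros
zscore0 <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
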