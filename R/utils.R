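# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible substream seed
#'
#' All stochastic operations take an explicit integer seed; nested draws
#' (per-dataset, per-condition) derive substream seeds from a master seed so
#' that conditions are paired across datasets. Kept below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param k substream index (>= 0)
#' @return an integer seed
#' @export
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65011) * 32749 + as.numeric(k) %% 32749 + 1)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  force(code)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Relative difference used throughout tests and diagnostics.
rel_err <- function(x, y) {
  d <- max(Mod(as.complex(x - y)))
  s <- max(Mod(as.complex(y)), 1e-300)
  d / s
}
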