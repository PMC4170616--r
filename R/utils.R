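## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ..., call. = FALSE) {
  if (cond) stop(..., call. = call.)
  invisible(TRUE)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## Standardize columns to zero mean / unit sd; constant columns become 0.
standardize_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}

## Derive a child seed from a base seed and stream indices, staying < 2^31.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 48271 + as.double(i)) %% 2147483647
  as.integer(s)
}
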