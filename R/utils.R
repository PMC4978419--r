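# Small shared helpers.

# Evaluate an expression under a local, restored RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)  # force RNG initialization
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage child seed from a master seed; stays below 2^31.
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(stage)) %% 2147483647
}

# Min-max normalize the columns of a matrix; constant columns map to 0.
# Returns the normalized matrix with the ranges attached, so query points
# can be mapped into the same coordinates.
normalize_minmax <- function(x, ranges = NULL) {
  x <- as.matrix(x)
  if (is.null(ranges)) {
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
  } else {
    lo <- ranges$lo; hi <- ranges$hi
  }
  span <- hi - lo
  span[span == 0] <- 1
  y <- sweep(sweep(x, 2, lo, "-"), 2, span, "/")
  attr(y, "ranges") <- list(lo = lo, hi = hi)
  y
}

# Shannon entropy (nats) of a nonnegative weight vector normalized to sum 1.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
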