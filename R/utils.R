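# Internal helpers shared across modules.

#' Raw median absolute deviation
#'
#' Plain `median(|x - median(x)|)` without the Gaussian consistency factor
#' 1.4826. All MAD-based thresholds and normalizations in this package
#' (artifact threshold, time-frequency map normalization) use this raw form.
#'
#' @param x numeric vector.
#' @return non-negative scalar.
#' @export
mad_raw <- function(x) {
  stats::median(abs(x - stats::median(x)))
}

# Half-open interval intersection: [a1, a2) vs [b1, b2).
# All epoch / window intersection logic in the package goes through this.
intervals_overlap <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & b_start < a_end
}

# TRUE for each row of `epochs` (matrix with columns start, end) that
# intersects any of the query intervals (vectors q_start, q_end).
any_overlap <- function(epochs, q_start, q_end) {
  if (is.null(epochs) || nrow(epochs) == 0L) return(logical(0))
  vapply(seq_len(nrow(epochs)), function(i) {
    any(intervals_overlap(epochs[i, 1L], epochs[i, 2L], q_start, q_end))
  }, logical(1))
}

# Run a block with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed derived from a master seed; kept < 2^31.
child_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + 7919 * as.double(index)) %% 2147483563) + 1L
}

# Maximal runs of TRUE in a logical vector -> matrix of [start_idx, end_idx]
# (inclusive indices). Used by the artifact detector.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Row-wise maximum of a numeric matrix (time x frequency), without
# matrixStats. pmax over a handful of columns is fast and allocation-light.
row_max <- function(m) {
  out <- m[, 1L]
  nc <- ncol(m)
  if (nc > 1L) for (j in 2L:nc) out <- pmax(out, m[, j])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
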