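# Internal helpers shared across modules.

#' Round half away from zero
#'
#' All count computations in the package (split sizes, flip counts, positives
#' in a synthetic dataset) use a single rounding rule: round half away from
#' zero. Base R's `round()` rounds half to even, which would make counts
#' platform- and value-dependent in surprising ways.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @examples
#' round_half_up(2.5)   # 3, where round(2.5) is 2
#' round_half_up(-2.5)  # -3
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a reproducible child seed
#'
#' Deterministic arithmetic hash used to give every (level, repetition,
#' pipeline) cell of an experiment its own RNG seed, so any single cell can
#' be recomputed in isolation. The hash is `(master * 1000003 + i * 10007 +
#' j * 101) mod (2^31 - 1)`, computed exactly in double precision; the result
#' always fits in a 32-bit integer.
#'
#' @param master integer master seed.
#' @param i,j integer indices (default 0).
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, i = 0L, j = 0L) {
  m <- 2147483647
  s <- (abs(as.numeric(master)) %% m) * 1000003 +
    abs(as.numeric(i)) * 10007 + abs(as.numeric(j)) * 101
  as.integer(s %% m)
}

# Run code with a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

stop_refnoise <- function(...) {
  stop(..., call. = FALSE)
}

# sd() guarded against zero-variance columns: a constant column gets scale 1
# so z-scoring maps it to exactly 0 rather than NaN.
safe_scale <- function(s) {
  ifelse(is.na(s) | s <= 0, 1, s)
}
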