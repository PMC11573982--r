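# Shared fixtures: tiny deterministic tables and small Gaussian two-class
# datasets built in code.

tiny_table <- function() {
  feature_table(matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
                       dimnames = list(c("a", "b", "c"), c("f1", "f2"))))
}

# Two-class Gaussian data: `d` is the standardized mean shift on the first
# `n_informative` features; the rest are pure noise. Returns a feature_table
# and reference_vector pair (balanced classes).
gauss_data <- function(n = 40, p = 5, d = 0, n_informative = 1, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(rnorm(n * p), n, p)
    if (n_informative > 0 && d != 0) {
      x[, seq_len(n_informative)] <- x[, seq_len(n_informative), drop = FALSE] + d * y
    }
    ids <- sprintf("s%04d", seq_len(n))
    list(table = feature_table(x, sample_ids = ids,
                               feature_names = sprintf("f%03d", seq_len(p))),
         ref = reference_vector(ids, y))
  })
}

# A reference vector with a given size and positive count.
make_ref <- function(n, n_pos, seed = 1) {
  withr::with_seed(seed, {
    y <- integer(n)
    y[sample.int(n, n_pos)] <- 1L
    reference_vector(sprintf("s%04d", seq_len(n)), y)
  })
}
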