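test_that("Mann-Whitney selection separates signal from constants and noise", {
  dat <- gauss_data(n = 40, p = 3, d = 0, seed = 3)
  x <- dat$table$values
  x[, 1] <- ifelse(dat$ref$labels == 1, x[, 1] + 100, x[, 1])  # perfect split
  x[, 2] <- 7                                                  # constant
  tab <- feature_table(x, dat$table$sample_ids, dat$table$feature_names)
  res <- select_mannwhitney(tab, dat$ref)
  expect_true("f001" %in% res$selected)
  expect_lt(res$scores[["f001"]], 1e-6)
  expect_false("f002" %in% res$selected)
  expect_equal(res$scores[["f002"]], 1)
})

test_that("Mann-Whitney p-values agree with the tie-corrected normal form of wilcox.test", {
  withr::with_seed(42, {
    for (i in 1:10) {
      n <- 30
      y <- rep(c(0L, 1L), each = n / 2)
      x <- round(rnorm(n, mean = 0.4 * y), 1)  # rounding induces ties
      tab <- feature_table(matrix(x, ncol = 1,
                                  dimnames = list(sprintf("s%02d", 1:n), "f1")))
      ours <- select_mannwhitney(tab, y)$scores[["f1"]]
      ref <- suppressWarnings(
        wilcox.test(x[y == 1], x[y == 0], exact = FALSE, correct = FALSE))$p.value
      expect_equal(ours, ref, tolerance = 1e-10)
    }
  })
})

test_that("Mann-Whitney falls back to all features when nothing passes", {
  dat <- gauss_data(n = 20, p = 3, d = 0, seed = 17)  # verified: no p < 0.05
  res <- select_mannwhitney(dat$table, dat$ref)
  expect_true(res$fallback_used)
  expect_setequal(res$selected, dat$table$feature_names)
})

test_that("lasso selection recovers a strong feature among noise", {
  hits <- 0L
  for (seed in 1:20) {
    dat <- gauss_data(n = 200, p = 21, d = 3, n_informative = 1, seed = seed)
    res <- select_lasso(dat$table, dat$ref, folds = 10, seed = seed)
    hits <- hits + ("f001" %in% res$selected)
  }
  expect_gte(hits, 19)
})

test_that("an infinite lasso penalty triggers the all-features fallback", {
  dat <- gauss_data(n = 50, p = 4, d = 1, seed = 2)
  res <- select_lasso(dat$table, dat$ref, lambda = 1e6)
  expect_true(res$fallback_used)
  expect_setequal(res$selected, dat$table$feature_names)
})

test_that("RFE keeps the signal-bearing feature and honours n_target", {
  dat <- gauss_data(n = 200, p = 3, d = 3, n_informative = 1, seed = 5)
  res <- select_rfe(dat$table, dat$ref, n_target = 1)
  expect_identical(res$selected, "f001")
  ident <- select_rfe(dat$table, dat$ref, n_target = 3)
  expect_setequal(ident$selected, dat$table$feature_names)
  again <- select_rfe(dat$table, dat$ref, n_target = 1)
  expect_identical(again$selected, res$selected)
  expect_identical(again$scores, res$scores)
})

test_that("mRMR penalizes an exact duplicate of the top feature", {
  dat <- gauss_data(n = 100, p = 4, d = 2, n_informative = 1, seed = 6)
  x <- dat$table$values
  x[, 2] <- x[, 1]  # identical copy: redundancy I(f;f) = H(f) dominates
  tab <- feature_table(x, dat$table$sample_ids, dat$table$feature_names)
  res <- select_mrmr(tab, dat$ref, n_target = 3)
  expect_equal(res$selected[1], "f001")
  expect_false(res$selected[2] == "f002")
})

test_that("mRMR first pick is symmetric over exchangeable null features", {
  picks <- vapply(1:150, function(seed) {
    dat <- gauss_data(n = 60, p = 5, d = 0, seed = 6000 + seed)
    select_mrmr(dat$table, dat$ref, n_target = 1)$selected
  }, character(1))
  tab <- table(factor(picks, levels = sprintf("f%03d", 1:5)))
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("multi-set Jaccard matches its definition and conventions", {
  expect_equal(jaccard_multi(list(c("1", "2", "3"), c("2", "3", "4"))), 0.5)
  expect_equal(jaccard_multi(rep(list(c("a", "b")), 20)), 1)
  expect_equal(jaccard_multi(list(c("a"), c("b"))), 0)
  expect_equal(jaccard_multi(list(character(0), character(0))), 1)
  expect_error(jaccard_multi(list(c("a"))), "at least 2")
  # permutation invariance and monotone non-increase as sets accumulate
  sets <- list(c("a", "b", "c"), c("b", "c"), c("b", "c", "d"))
  expect_equal(jaccard_multi(sets), jaccard_multi(rev(sets)))
  expect_lte(jaccard_multi(sets), jaccard_multi(sets[1:2]))
})

test_that("every selector recovers at least half the informative features at level 0", {
  ds <- generate_synthetic(profile_dataset1(), seed = 31)
  split <- stratified_split(ds$features, ds$labels, seed = 32)
  tab <- subset_table(ds$features, split$train_ids)
  ref <- subset_reference(ds$labels, split$train_ids)
  truth <- ds$truth$feature
  for (m in c("mannwhitney", "rfe", "lasso", "mrmr")) {
    sel <- select_features(tab, ref, method = m, n_target = 30, seed = 33)
    expect_gte(sum(truth %in% sel$selected), 5)
  }
})

test_that("selection results serialize to a per-feature CSV", {
  dat <- gauss_data(n = 30, p = 4, d = 2, seed = 8)
  res <- select_mannwhitney(dat$table, dat$ref)
  path <- withr::local_tempfile(fileext = ".csv")
  write_selection(res, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 4)
  expect_setequal(back$feature[back$selected == 1], res$selected)
})
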