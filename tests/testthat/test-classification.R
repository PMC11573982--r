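test_that("both classifiers separate strong signal out of fold", {
  dat <- gauss_data(n = 200, p = 5, d = 3, n_informative = 2, seed = 1)
  sel <- select_mannwhitney(dat$table, dat$ref)
  for (cl in c("rf", "lasso_logistic")) {
    spec <- pipeline_spec("mannwhitney", cl, cv_folds = 10, seed = 2)
    ps <- crossval_train(dat$table, dat$ref, sel, spec)
    expect_gte(roc_auc(ps$oof_scores, dat$ref$labels), 0.95)
    expect_true(all(ps$oof_scores >= 0 & ps$oof_scores <= 1))
  }
})

test_that("out-of-fold AUC against shuffled labels sits at the null value", {
  dat <- gauss_data(n = 260, p = 10, d = 0, seed = 3)
  sel <- select_mannwhitney(dat$table, dat$ref, alpha = 1)  # fixed feature set
  shuffled <- withr::with_seed(4, {
    reference_vector(dat$ref$sample_ids, sample(dat$ref$labels))
  })
  spec <- pipeline_spec("mannwhitney", "lasso_logistic", cv_folds = 10, seed = 5)
  ps <- crossval_train(dat$table, shuffled, sel, spec)
  expect_gt(roc_auc(ps$oof_scores, shuffled$labels), 0.45)
  expect_lt(roc_auc(ps$oof_scores, shuffled$labels), 0.55)
})

test_that("training is deterministic given the pipeline seed", {
  dat <- gauss_data(n = 80, p = 6, d = 1, n_informative = 2, seed = 6)
  sel <- select_mannwhitney(dat$table, dat$ref, alpha = 1)
  for (cl in c("rf", "lasso_logistic")) {
    spec <- pipeline_spec("mannwhitney", cl, cv_folds = 5, seed = 7)
    a <- crossval_train(dat$table, dat$ref, sel, spec)
    b <- crossval_train(dat$table, dat$ref, sel, spec)
    expect_identical(a$oof_scores, b$oof_scores)
    expect_identical(a$fold_assignment, b$fold_assignment)
  }
})

test_that("fold assignment is label-stratified to within one sample", {
  dat <- gauss_data(n = 95, p = 2, d = 0, seed = 8)
  ref <- make_ref(95, 38, seed = 9)
  sel <- select_mannwhitney(dat$table, ref, alpha = 1)
  spec <- pipeline_spec("mannwhitney", "lasso_logistic", cv_folds = 5, seed = 10)
  ps <- crossval_train(dat$table, ref, sel, spec)
  per_fold <- table(ps$fold_assignment, ref$labels)
  for (cl in 1:2) {
    expect_lte(diff(range(per_fold[, cl])), 1)
  }
})

test_that("resubstitution scoring is at least as optimistic as out-of-fold", {
  dat <- gauss_data(n = 100, p = 5, d = 1.5, n_informative = 2, seed = 11)
  sel <- select_mannwhitney(dat$table, dat$ref)
  spec <- pipeline_spec("mannwhitney", "rf", cv_folds = 5, seed = 12)
  ps <- crossval_train(dat$table, dat$ref, sel, spec)
  resub <- predict_holdout(ps, dat$table)  # test set == training set
  expect_gte(roc_auc(resub, dat$ref$labels),
             roc_auc(ps$oof_scores, dat$ref$labels))
})

test_that("hold-out prediction checks features and handles a single sample", {
  dat <- gauss_data(n = 60, p = 4, d = 2, seed = 13)
  sel <- select_mannwhitney(dat$table, dat$ref)
  spec <- pipeline_spec("mannwhitney", "lasso_logistic", cv_folds = 5, seed = 14)
  ps <- crossval_train(dat$table, dat$ref, sel, spec)
  one <- feature_table(dat$table$values[1, , drop = FALSE],
                       "new1", dat$table$feature_names)
  s <- predict_holdout(ps, one)
  expect_length(s, 1)
  expect_true(s >= 0 && s <= 1)
  crippled <- feature_table(dat$table$values[, -1, drop = FALSE],
                            dat$table$sample_ids, dat$table$feature_names[-1])
  if ("f001" %in% ps$selected) {
    expect_error(predict_holdout(ps, crippled), "f001")
  }
})

test_that("hold-out rows cannot influence training or selection", {
  ds <- generate_synthetic(dataset_profile("t", 120, 20, 0.5,
                                           n_informative = 4,
                                           effect_size = 1.5), seed = 15)
  split <- stratified_split(ds$features, ds$labels, seed = 16)
  poisoned <- ds$features$values
  poisoned[split$test_ids, ] <- 1e6  # sentinel values in every hold-out row
  ptab <- feature_table(poisoned, ds$features$sample_ids,
                        ds$features$feature_names)
  run <- function(tab) {
    tr <- subset_table(tab, split$train_ids)
    ref <- subset_reference(ds$labels, split$train_ids)
    sel <- select_mannwhitney(tr, ref)
    spec <- pipeline_spec("mannwhitney", "lasso_logistic", cv_folds = 5,
                          seed = 17)
    list(sel = sel$selected,
         oof = crossval_train(tr, ref, sel, spec)$oof_scores)
  }
  clean <- run(ds$features)
  dirty <- run(ptab)
  expect_identical(dirty$sel, clean$sel)
  expect_identical(dirty$oof, clean$oof)
})

test_that("fold count is reduced with a warning when the minority class is small", {
  dat <- gauss_data(n = 40, p = 3, d = 1, seed = 18)
  ref <- make_ref(40, 6, seed = 19)
  sel <- select_mannwhitney(dat$table, ref, alpha = 1)
  spec <- pipeline_spec("mannwhitney", "rf", cv_folds = 10, seed = 20)
  expect_warning(ps <- crossval_train(dat$table, ref, sel, spec),
                 "reducing cv folds")
  expect_equal(max(ps$fold_assignment), 6)
})
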