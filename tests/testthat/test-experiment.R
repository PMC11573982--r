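# Small-scale end-to-end runs; the full-scale study conditions are exercised
# in test-acceptance.R.

small_profile <- function() {
  dataset_profile("small", n_samples = 80, n_features = 30, prevalence = 0.5,
                  n_informative = 5, effect_size = 1.5, block_size = 5,
                  block_rho = 0.8)
}

test_that("the factorial run produces one record per cell and surface", {
  cfg <- experiment_config(dataset = small_profile(), seed = 101,
                           levels = c(0, 0.2), repetitions = 3,
                           selectors = c("mannwhitney", "mrmr"),
                           classifiers = c("rf", "lasso_logistic"))
  res <- run_experiment(cfg)
  # levels x reps x (selectors x classifiers) x surfaces
  expect_equal(nrow(res$metrics), 2 * 3 * 4 * 3)
  expect_setequal(unique(res$metrics$surface),
                  c("train_vs_permuted", "train_vs_true", "holdout_vs_true"))
  expect_true(all(res$metrics$auc >= 0 & res$metrics$auc <= 1))
  expect_equal(nrow(res$jsc), 4)   # 2 selectors x 2 levels
  expect_true(all(res$jsc$n_sets == 3))
  # identical config reproduces identical outputs
  res2 <- run_experiment(cfg)
  expect_identical(res2$metrics, res$metrics)
  expect_identical(res2$jsc, res$jsc)
})

test_that("level-0 repetitions are identical", {
  cfg <- experiment_config(dataset = small_profile(), seed = 102,
                           levels = 0, repetitions = 2,
                           selectors = "mannwhitney", classifiers = "rf")
  res <- run_experiment(cfg)
  by_rep <- split(res$metrics$auc, res$metrics$repetition)
  expect_identical(by_rep[[1]], by_rep[[2]])
})

test_that("summaries aggregate repetitions per pipeline, surface and level", {
  cfg <- experiment_config(dataset = small_profile(), seed = 103,
                           levels = c(0, 0.3), repetitions = 3,
                           selectors = "mannwhitney",
                           classifiers = "lasso_logistic")
  res <- run_experiment(cfg)
  smry <- summarize_experiment(res)
  expect_equal(nrow(smry$metrics), 1 * 3 * 2)  # pipelines x surfaces x levels
  lev0 <- smry$metrics[smry$metrics$level == 0, ]
  expect_true(all(lev0$auc_sd == 0))           # deterministic level 0
  expect_true(all(c("proportion_selected", "jsc") %in% names(smry$selection)))
  dir <- withr::local_tempdir()
  write_experiment(res, dir)
  expect_true(all(file.exists(file.path(dir,
    c("metrics.csv", "jsc.csv", "selection.csv", "manifest.json")))))
})

test_that("selection-only runs support stability studies without classifiers", {
  cfg <- experiment_config(dataset = small_profile(), seed = 104,
                           levels = c(0, 0.25), repetitions = 4,
                           selectors = "lasso", classifiers = character(0))
  res <- run_experiment(cfg)
  expect_equal(nrow(res$metrics), 0)
  expect_equal(nrow(res$jsc), 2)
  expect_equal(res$jsc$jsc[res$jsc$level == 0], 1)
})

test_that("Mann-Whitney selects about alpha of features on pure-noise data", {
  null_prof <- dataset_profile("null", n_samples = 200, n_features = 200,
                               prevalence = 0.5, n_informative = 0,
                               effect_size = 0)
  cfg <- experiment_config(dataset = null_prof, seed = 105, levels = 0,
                           repetitions = 1, selectors = "mannwhitney",
                           classifiers = character(0))
  res <- run_experiment(cfg)
  prop <- res$selection$proportion_selected[1]
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(prop - 0.05), 3 * se)
})

test_that("configs validate selector and classifier names", {
  expect_error(experiment_config(selectors = "boruta"), "selectors")
  expect_error(experiment_config(classifiers = "svm"), "classifiers")
})

test_that("YAML configs map onto the same experiment definition", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("dataset: dataset1", "seed: 7", "repetitions: 5",
               "selectors: [mannwhitney, lasso]",
               "classifiers: [lasso_logistic]"), path)
  cfg <- read_experiment_config(path)
  expect_s3_class(cfg$dataset, "dataset_profile")
  expect_equal(cfg$dataset$n_samples, 260L)
  expect_equal(cfg$repetitions, 5L)
  expect_identical(cfg$selectors, c("mannwhitney", "lasso"))
})

test_that("the small high-dimensional profile is the more variable regime", {
  # matched levels, same pipeline: between-repetition SD should be larger
  # for the 100 x 7106 profile than for the 260 x 265 profile
  base <- list(levels = c(0.1, 0.2), repetitions = 6,
               selectors = "mannwhitney", classifiers = "lasso_logistic")
  res1 <- run_experiment(do.call(experiment_config,
                                 c(list(dataset = profile_dataset1(),
                                        seed = 106), base)))
  res2 <- run_experiment(do.call(experiment_config,
                                 c(list(dataset = profile_dataset2(),
                                        seed = 106), base)))
  sd_of <- function(res) {
    m <- res$metrics[res$metrics$surface == "holdout_vs_true", ]
    mean(vapply(split(m$auc, m$level), sd, numeric(1)))
  }
  expect_gt(sd_of(res2) / sd_of(res1), 1)
})
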