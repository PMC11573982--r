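# Orchestration: the full factorial experiment over permutation levels,
# repetitions, pipelines and evaluation surfaces, plus summaries and plots.

#' Configure an experiment
#'
#' Bundles everything needed for a reproducible run: the data source (a
#' [dataset_profile] to simulate, or paths to feature/label CSVs), the
#' train/hold-out split, the permutation plan, which selectors and
#' classifiers to cross, and their parameters. A single master `seed`
#' drives every random component through [derive_seed()], so re-running an
#' identical config reproduces identical outputs.
#'
#' @param dataset a [dataset_profile], or a list `list(features =, labels =)`
#'   of CSV paths.
#' @param seed master integer seed.
#' @param split_ratio training fraction (default 0.7).
#' @param levels permutation levels (default 0 to 0.5 in 0.05 steps).
#' @param repetitions repetitions per level (default 20).
#' @param selectors subset of `c("mannwhitney", "rfe", "lasso", "mrmr")`.
#' @param classifiers subset of `c("rf", "lasso_logistic")`; may be empty
#'   (`character(0)`) for a selection-stability-only run.
#' @param n_target subset size for rfe/mrmr; `NULL` means
#'   `min(30, floor(n_train / 5))`.
#' @param cv_folds outer cross-validation folds; `NULL` means 10 when the
#'   training set has >= 150 samples, otherwise 5.
#' @param alpha Mann-Whitney selection threshold.
#' @param cutoff score cutoff for accuracy/sensitivity/specificity.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(dataset = profile_dataset1(), seed = 1L,
                              split_ratio = 0.7,
                              levels = seq(0, 0.5, by = 0.05),
                              repetitions = 20L,
                              selectors = c("mannwhitney", "rfe", "lasso", "mrmr"),
                              classifiers = c("rf", "lasso_logistic"),
                              n_target = NULL, cv_folds = NULL,
                              alpha = 0.05, cutoff = 0.5) {
  ok_sel <- c("mannwhitney", "rfe", "lasso", "mrmr")
  if (length(selectors) == 0 || !all(selectors %in% ok_sel)) {
    stop_refnoise("selectors must be a non-empty subset of: ",
                  paste(ok_sel, collapse = ", "))
  }
  if (!all(classifiers %in% c("rf", "lasso_logistic"))) {
    stop_refnoise("classifiers must be a subset of: rf, lasso_logistic")
  }
  structure(list(dataset = dataset, seed = as.integer(seed),
                 split_ratio = split_ratio, levels = as.numeric(levels),
                 repetitions = as.integer(repetitions),
                 selectors = selectors, classifiers = classifiers,
                 n_target = n_target, cv_folds = cv_folds,
                 alpha = alpha, cutoff = cutoff),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Fields mirror the arguments of [experiment_config()]; `dataset` may be
#' the string `"dataset1"` or `"dataset2"`, a mapping of [dataset_profile()]
#' arguments, or a mapping with `features`/`labels` CSV paths.
#'
#' @param path path to a YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_refnoise("reading YAML configs requires the 'yaml' package")
  }
  cfg <- yaml::read_yaml(path)
  ds <- cfg$dataset
  if (is.character(ds) && length(ds) == 1) {
    ds <- switch(ds, dataset1 = profile_dataset1(),
                 dataset2 = profile_dataset2(),
                 stop_refnoise("unknown dataset profile: ", ds))
  } else if (is.list(ds) && !is.null(ds$features)) {
    ds <- list(features = ds$features, labels = ds$labels)
  } else if (is.list(ds)) {
    ds <- do.call(dataset_profile, ds)
  }
  cfg$dataset <- ds
  args <- cfg[intersect(names(cfg), names(formals(experiment_config)))]
  do.call(experiment_config, args)
}

# Materialize the configured data source.
load_dataset <- function(config) {
  if (inherits(config$dataset, "dataset_profile")) {
    ds <- generate_synthetic(config$dataset, seed = derive_seed(config$seed, 11L))
    list(table = ds$features, ref = ds$labels, truth = ds$truth,
         name = config$dataset$name)
  } else {
    table <- read_feature_table(config$dataset$features)
    ref <- read_reference(config$dataset$labels, table)
    list(table = table, ref = ref, truth = NULL, name = "user_csv")
  }
}

# Run every configured pipeline for one permuted reference; returns the
# metric rows plus each selector's selected set.
run_cell <- function(train_tab, test_tab, train_ref_true, test_ref, perm,
                     config, n_target, cv_folds, level_index) {
  records <- list()
  selections <- list()
  cell_seed <- derive_seed(config$seed, 100L + level_index, perm$repetition)
  for (sel in config$selectors) {
    selection <- select_features(train_tab, perm, method = sel,
                                 n_target = n_target, alpha = config$alpha,
                                 folds = cv_folds,
                                 seed = derive_seed(cell_seed, 1L))
    selections[[sel]] <- selection
    # per-fold re-selection keeps the out-of-fold training surfaces free of
    # selection leakage; the full-training-set selection above feeds the
    # stability statistic and the hold-out model
    selector_fun <- local({
      method <- sel
      function(tab, labels) {
        select_features(tab, labels, method = method, n_target = n_target,
                        alpha = config$alpha, folds = cv_folds,
                        seed = derive_seed(cell_seed, 4L))
      }
    })
    for (ci in seq_along(config$classifiers)) {
      cl <- config$classifiers[ci]
      spec <- pipeline_spec(sel, cl, cv_folds = cv_folds,
                            seed = derive_seed(cell_seed, 2L, ci))
      pset <- crossval_train(train_tab, perm, selection, spec, selector_fun)
      holdout <- predict_holdout(pset, test_tab)
      surfaces <- list(
        train_vs_permuted = list(scores = pset$oof_scores,
                                 labels = perm$labels),
        train_vs_true = list(scores = pset$oof_scores,
                             labels = train_ref_true$labels),
        holdout_vs_true = list(scores = holdout, labels = test_ref$labels))
      for (sf in names(surfaces)) {
        row <- metric_row(surfaces[[sf]]$scores, surfaces[[sf]]$labels,
                          config$cutoff)
        row <- cbind(data.frame(pipeline = spec$id, selector = sel,
                                classifier = cl, surface = sf,
                                level = perm$level,
                                repetition = perm$repetition), row)
        records[[length(records) + 1L]] <- row
      }
    }
  }
  sel_rows <- do.call(rbind, lapply(config$selectors, function(s) {
    data.frame(selector = s, level = perm$level,
               repetition = perm$repetition,
               n_selected = length(selections[[s]]$selected),
               proportion_selected = length(selections[[s]]$selected) /
                 n_features(train_tab),
               fallback_used = selections[[s]]$fallback_used)
  }))
  list(metrics = if (length(records)) do.call(rbind, records) else NULL,
       selection = sel_rows,
       selected_sets = lapply(selections, function(s) s$selected))
}

#' Run the full reference-uncertainty experiment
#'
#' For every (level, repetition) cell of the plan: permute the training
#' references (the hold-out labels are never touched), run feature selection
#' once per selector on the permuted training set, train each configured
#' classifier under stratified cross-validation, and record AUC, accuracy,
#' sensitivity and specificity on the three evaluation surfaces —
#' out-of-fold scores against the permuted labels (`train_vs_permuted`),
#' the same scores against the true training labels (`train_vs_true`), and
#' hold-out scores from the final refit model against the true hold-out
#' labels (`holdout_vs_true`). Per (selector, level), the multi-set Jaccard
#' similarity of the repetitions' selected sets is computed. Level-0 cells
#' are deterministic, so the first repetition is computed and replicated.
#'
#' @param config an [experiment_config].
#' @return an object of class `refnoise_result`: data.frames `metrics`
#'   (one row per pipeline x surface x level x repetition), `jsc`
#'   (selector x level), `selection` (selected-set sizes and fallback
#'   flags), plus `config`, `split`, `n_train`, `train_prevalence`, and a
#'   `manifest` of seeds and versions.
#' @export
run_experiment <- function(config) {
  data <- load_dataset(config)
  split <- stratified_split(data$table, data$ref, ratio = config$split_ratio,
                            seed = derive_seed(config$seed, 12L))
  train_tab <- subset_table(data$table, split$train_ids)
  test_tab <- subset_table(data$table, split$test_ids)
  train_ref <- subset_reference(data$ref, split$train_ids)
  test_ref <- subset_reference(data$ref, split$test_ids)
  n_train <- length(split$train_ids)
  n_target <- config$n_target %||% min(30L, n_train %/% 5L)
  cv_folds <- config$cv_folds %||% (if (n_train >= 150) 10L else 5L)

  plan <- permutation_plan(config$levels, config$repetitions,
                           master_seed = derive_seed(config$seed, 13L))
  metrics <- list()
  selection <- list()
  sets <- list()  # sets[[selector]][[level]][[rep]]
  for (li in seq_along(plan$levels)) {
    level <- plan$levels[li]
    level0_cell <- NULL
    for (ri in seq_len(plan$repetitions)) {
      if (level == 0 && ri > 1L) {
        # level 0 is the identity permutation: every repetition is the same
        # computation, so replicate the first with the repetition re-indexed
        cell <- level0_cell
        if (!is.null(cell$metrics)) cell$metrics$repetition <- ri
        cell$selection$repetition <- ri
      } else {
        perm <- permute_reference(train_ref, level,
                                  seed = derive_seed(plan$master_seed, li, ri),
                                  repetition = ri)
        stopifnot(all(perm$sample_ids %in% split$train_ids))
        cell <- run_cell(train_tab, test_tab, train_ref, test_ref, perm,
                         config, n_target, cv_folds, li)
        if (level == 0 && ri == 1L) level0_cell <- cell
      }
      if (!is.null(cell$metrics)) metrics[[length(metrics) + 1L]] <- cell$metrics
      selection[[length(selection) + 1L]] <- cell$selection
      for (s in names(cell$selected_sets)) {
        key <- sprintf("%s@%g", s, level)
        sets[[key]] <- c(sets[[key]], list(cell$selected_sets[[s]]))
      }
    }
  }
  jsc <- do.call(rbind, lapply(names(sets), function(key) {
    parts <- strsplit(key, "@", fixed = TRUE)[[1]]
    data.frame(selector = parts[1], level = as.numeric(parts[2]),
               jsc = if (length(sets[[key]]) >= 2) jaccard_multi(sets[[key]])
                     else NA_real_,
               n_sets = length(sets[[key]]))
  }))
  jsc <- jsc[order(jsc$selector, jsc$level), ]
  rownames(jsc) <- NULL
  metrics_df <- if (length(metrics)) do.call(rbind, metrics) else
    data.frame()
  rownames(metrics_df) <- NULL
  selection_df <- do.call(rbind, selection)
  rownames(selection_df) <- NULL
  structure(list(
    metrics = metrics_df, jsc = jsc, selection = selection_df,
    selected_sets = sets, config = config, split = split,
    dataset_name = data$name, n_train = n_train,
    train_prevalence = prevalence(train_ref),
    n_target = n_target, cv_folds = cv_folds,
    manifest = list(seed = config$seed,
                    package_version = as.character(utils::packageVersion("refnoise")),
                    r_version = R.version.string)),
    class = "refnoise_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.refnoise_result <- function(x, ...) {
  cat(sprintf(paste0("<refnoise_result> %s: %d metric records ",
                     "(%d levels x %d repetitions), %d train / %d test\n"),
              x$dataset_name, nrow(x$metrics), length(x$config$levels),
              x$config$repetitions, x$n_train,
              length(x$split$test_ids)))
  invisible(x)
}

#' Summarize an experiment
#'
#' Aggregates over repetitions: per (pipeline, surface, level) the mean,
#' SD, min and max of each metric, and per (selector, level) the mean
#' proportion of features selected and the repetition-level Jaccard
#' stability.
#'
#' @param result a `refnoise_result`.
#' @return a list of data.frames `metrics` and `selection`.
#' @export
summarize_experiment <- function(result) {
  m <- result$metrics
  metric_summary <- NULL
  if (nrow(m) > 0) {
    agg <- function(fun, name) {
      out <- stats::aggregate(m[c("auc", "accuracy", "sensitivity", "specificity")],
                              by = m[c("pipeline", "surface", "level")], FUN = fun)
      names(out)[4:7] <- paste0(c("auc", "accuracy", "sensitivity",
                                  "specificity"), "_", name)
      out
    }
    metric_summary <- Reduce(function(a, b) merge(a, b,
                                                  by = c("pipeline", "surface", "level")),
                             list(agg(mean, "mean"), agg(stats::sd, "sd"),
                                  agg(min, "min"), agg(max, "max")))
    metric_summary <- metric_summary[order(metric_summary$pipeline,
                                           metric_summary$surface,
                                           metric_summary$level), ]
    rownames(metric_summary) <- NULL
  }
  s <- result$selection
  sel_summary <- stats::aggregate(
    s[c("proportion_selected", "n_selected")],
    by = s[c("selector", "level")], FUN = mean)
  sel_summary <- merge(sel_summary, result$jsc,
                       by = c("selector", "level"), all.x = TRUE)
  sel_summary <- sel_summary[order(sel_summary$selector, sel_summary$level), ]
  rownames(sel_summary) <- NULL
  list(metrics = metric_summary, selection = sel_summary)
}

#' Mean metric per level for one pipeline and surface
#'
#' Convenience accessor used throughout the tests and the acceptance
#' script: the per-level mean of a metric over repetitions.
#'
#' @param result a `refnoise_result`.
#' @param pipeline pipeline id, e.g. `"mannwhitney+lasso_logistic"`.
#' @param surface one of `"train_vs_permuted"`, `"train_vs_true"`,
#'   `"holdout_vs_true"`.
#' @param metric metric column name (default `"auc"`).
#' @return data.frame with columns `level`, `mean`, `sd`.
#' @export
level_means <- function(result, pipeline, surface, metric = "auc") {
  m <- result$metrics
  m <- m[m$pipeline == pipeline & m$surface == surface, ]
  if (nrow(m) == 0) stop_refnoise("no records for ", pipeline, " / ", surface)
  out <- do.call(rbind, lapply(split(m[[metric]], m$level), function(v) {
    data.frame(mean = mean(v), sd = stats::sd(v))
  }))
  data.frame(level = as.numeric(rownames(out)), mean = out$mean, sd = out$sd,
             row.names = NULL)
}

#' Write experiment outputs to a directory
#'
#' Emits `metrics.csv`, `jsc.csv`, `selection.csv`, the two summary tables,
#' and `manifest.json` (master seed, package and R versions, config).
#'
#' @param result a `refnoise_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$jsc, file.path(dir, "jsc.csv"), row.names = FALSE)
  utils::write.csv(result$selection, file.path(dir, "selection.csv"),
                   row.names = FALSE)
  smry <- summarize_experiment(result)
  if (!is.null(smry$metrics)) {
    utils::write.csv(smry$metrics, file.path(dir, "metrics_summary.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(smry$selection, file.path(dir, "selection_summary.csv"),
                   row.names = FALSE)
  cfg <- result$config
  cfg$dataset <- if (inherits(cfg$dataset, "dataset_profile")) {
    unclass(cfg$dataset)
  } else cfg$dataset
  jsonlite::write_json(c(result$manifest, list(config = unclass(cfg))),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Plot mean metric degradation across permutation levels
#'
#' A Figs. 2-7-style panel: per-level mean with an SD ribbon for each
#' pipeline on one evaluation surface. Requires ggplot2.
#'
#' @param result a `refnoise_result`.
#' @param surface evaluation surface to plot.
#' @param metric metric column (default `"auc"`).
#' @return a ggplot object.
#' @export
plot_level_curves <- function(result, surface = "train_vs_permuted",
                              metric = "auc") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_refnoise("plotting requires the 'ggplot2' package")
  }
  m <- result$metrics[result$metrics$surface == surface, ]
  agg <- stats::aggregate(m[[metric]], by = m[c("pipeline", "level")],
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  df <- data.frame(pipeline = agg$pipeline, level = agg$level,
                   mean = agg$x[, "mean"], sd = agg$x[, "sd"])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$mean,
                                   colour = .data$pipeline,
                                   fill = .data$pipeline)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "reference permutation level",
                  y = paste("mean", metric), title = surface) +
    ggplot2::theme_minimal()
}
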