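# The two classifiers behind one interface, stratified cross-validation on
# (possibly permuted) training labels, and hold-out scoring.
#
# Anti-leakage rules: feature selection happens before this module sees the
# data; z-scoring for the lasso-logistic classifier uses training statistics
# only, re-estimated inside each cross-validation fold; hold-out samples
# never influence fold models, the final model, or any transform.

#' Describe one (selector, classifier) pipeline
#'
#' @param selector selector name (`"mannwhitney"`, `"rfe"`, `"lasso"`,
#'   `"mrmr"`).
#' @param classifier `"rf"` (random forest, 500 trees, sqrt(p) candidate
#'   features per split) or `"lasso_logistic"` (L1-penalized logistic
#'   regression, penalty chosen by inner stratified cross-validation).
#' @param cv_folds outer cross-validation folds.
#' @param seed integer seed controlling folds and classifier randomness.
#' @return an object of class `pipeline_spec`.
#' @export
pipeline_spec <- function(selector, classifier = c("rf", "lasso_logistic"),
                          cv_folds = 10L, seed = 1L) {
  classifier <- match.arg(classifier)
  structure(list(selector = selector, classifier = classifier,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 id = paste(selector, classifier, sep = "+")),
            class = "pipeline_spec")
}

#' The full selector-by-classifier grid
#'
#' Crosses the four selectors with the two classifiers into the eight
#' benchmark pipelines.
#'
#' @param selectors selector names.
#' @param classifiers classifier names.
#' @param cv_folds,seed passed to [pipeline_spec()].
#' @return a named list of `pipeline_spec` objects.
#' @export
pipeline_grid <- function(selectors = c("mannwhitney", "rfe", "lasso", "mrmr"),
                          classifiers = c("rf", "lasso_logistic"),
                          cv_folds = 10L, seed = 1L) {
  out <- list()
  for (s in selectors) {
    for (cl in classifiers) {
      spec <- pipeline_spec(s, cl, cv_folds = cv_folds, seed = seed)
      out[[spec$id]] <- spec
    }
  }
  out
}

# Fit one classifier on a numeric matrix; returns a self-contained model
# object able to score new data on the same features.
fit_classifier <- function(classifier, x, y, seed, inner_folds = 5L) {
  if (classifier == "rf") {
    fit <- with_seed(seed, {
      randomForest::randomForest(
        x, factor(y, levels = c(0, 1)), ntree = 500,
        mtry = max(1L, floor(sqrt(ncol(x)))))
    })
    list(classifier = "rf", fit = fit, features = colnames(x))
  } else {
    pad <- ncol(x) == 1L  # glmnet needs >= 2 columns; a zero column is inert
    if (pad) x <- cbind(x, `.pad` = 0)
    z <- zscore_fit(x)
    k <- max(3L, min(as.integer(inner_folds), min(table(y))))
    foldid <- stratified_folds(y, k, seed = seed)
    cv <- glmnet::cv.glmnet(z$x, y, family = "binomial", alpha = 1,
                            foldid = foldid, type.measure = "deviance",
                            standardize = FALSE, nlambda = 50,
                            lambda.min.ratio = 0.01)
    # lambda.1se: the strongest penalty within one SE of the deviance
    # optimum — materially more robust to label noise than lambda.min
    list(classifier = "lasso_logistic", fit = cv, lambda = cv$lambda.1se,
         center = z$center, scale = z$scale, pad = pad,
         features = setdiff(colnames(x), ".pad"))
  }
}

predict_classifier <- function(model, x) {
  if (model$classifier == "rf") {
    unname(stats::predict(model$fit, x, type = "prob")[, "1"])
  } else {
    if (isTRUE(model$pad)) x <- cbind(x, `.pad` = 0)
    zx <- zscore_apply(x, model$center, model$scale)
    as.numeric(stats::predict(model$fit, zx, s = model$lambda,
                              type = "response"))
  }
}

#' Cross-validated training on (permuted) labels
#'
#' Runs stratified K-fold cross-validation on the supplied labels: each fold
#' model is fit on the complementary folds (restricted to the selected
#' features) and scores its own fold, giving every training sample exactly
#' one out-of-fold class-1 probability. A final model is then refit on the
#' full training set for hold-out scoring. If the minority class has fewer
#' members than `cv_folds`, K is reduced to the minority count (warning).
#'
#' When `selector_fun` is supplied, feature selection is repeated inside
#' every fold on that fold's training samples only, so the out-of-fold
#' scores carry no selection leakage from the evaluated fold; the supplied
#' `selection` is then used only for the final refit model (whose job is
#' hold-out scoring, where the hold-out samples played no part in
#' selection either way).
#'
#' @param table training [feature_table].
#' @param ref training labels (typically a `permuted_reference`), aligned to
#'   `table`.
#' @param selection a `selection_result` restricting the feature set.
#' @param spec a [pipeline_spec].
#' @param selector_fun optional `function(table, labels)` returning a
#'   `selection_result`, re-run inside each fold (see above). `NULL`
#'   (default) uses `selection` for the fold models too.
#' @return an object of class `prediction_set`: `oof_scores` (named, one per
#'   training sample), `fold_assignment`, `model` (final refit model),
#'   `spec`, `selected`.
#' @export
crossval_train <- function(table, ref, selection, spec, selector_fun = NULL) {
  y <- as_labels(ref, table)
  if (length(selection$selected) == 0) stop_refnoise("empty selection")
  x <- table$values[, selection$selected, drop = FALSE]
  minority <- min(table(y))
  k <- spec$cv_folds
  if (minority < k) {
    warning("reducing cv folds from ", k, " to minority-class count ",
            minority, call. = FALSE)
    k <- max(2L, as.integer(minority))
  }
  folds <- stratified_folds(y, k, seed = derive_seed(spec$seed, 1L))
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    in_fold <- folds == f
    if (is.null(selector_fun)) {
      x_f <- x
    } else {
      fold_tab <- subset_table(table, table$sample_ids[!in_fold])
      fold_sel <- selector_fun(fold_tab, y[!in_fold])
      x_f <- table$values[, fold_sel$selected, drop = FALSE]
    }
    model_f <- fit_classifier(spec$classifier, x_f[!in_fold, , drop = FALSE],
                              y[!in_fold], seed = derive_seed(spec$seed, 2L, f))
    oof[in_fold] <- predict_classifier(model_f, x_f[in_fold, , drop = FALSE])
  }
  names(oof) <- table$sample_ids
  final <- fit_classifier(spec$classifier, x, y,
                          seed = derive_seed(spec$seed, 3L))
  names(folds) <- table$sample_ids
  structure(list(oof_scores = oof, fold_assignment = folds, model = final,
                 spec = spec, selected = selection$selected),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %s: %d out-of-fold scores over %d folds\n",
              x$spec$id, length(x$oof_scores), max(x$fold_assignment)))
  invisible(x)
}

#' Score a hold-out set with the final refit model
#'
#' Applies the model refit on the full (permuted-label) training set to new
#' samples. Transformations (z-scoring for the lasso-logistic classifier)
#' use training statistics only.
#'
#' @param pset a `prediction_set` from [crossval_train()] (or its `model`).
#' @param test_table hold-out [feature_table]; must contain every selected
#'   feature.
#' @return named numeric vector of class-1 scores in \[0, 1\], one per
#'   hold-out sample.
#' @export
predict_holdout <- function(pset, test_table) {
  model <- if (inherits(pset, "prediction_set")) pset$model else pset
  missing <- setdiff(model$features, test_table$feature_names)
  if (length(missing) > 0) {
    stop_refnoise("hold-out table is missing selected feature(s): ",
                  paste(utils::head(missing, 5), collapse = ", "))
  }
  x <- test_table$values[, model$features, drop = FALSE]
  scores <- predict_classifier(model, x)
  names(scores) <- test_table$sample_ids
  scores
}
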