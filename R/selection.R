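# The four feature selectors of the benchmarked grid, each returning a
# selection_result, plus the multi-set Jaccard similarity used to quantify
# selection stability across permutation repetitions.
#
# Every selector guarantees a non-empty selection: if its own rule selects
# nothing (all p-values above alpha, an empty lasso model), it returns all
# features and flags fallback_used. This fallback is part of the studied
# behaviour — an all-features fallback produces a Jaccard similarity of 1
# across repetitions whenever every repetition falls back.

selection_result <- function(method, selected, scores, fallback_used = FALSE) {
  structure(list(method = method, selected = as.character(selected),
                 scores = scores, fallback_used = isTRUE(fallback_used)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d features selected%s\n", x$method,
              length(x$selected),
              if (x$fallback_used) " (fallback: all features)" else ""))
  invisible(x)
}

# Vectorized two-sided Mann-Whitney U p-values (midranks, tie-corrected
# normal approximation, no continuity correction) for every column of x
# against binary y. Constant columns get p = 1.
mw_pvalues <- function(x, y) {
  n <- nrow(x)
  n1 <- sum(y == 1L)
  n0 <- n - n1
  ranks <- apply(x, 2L, rank)           # midranks
  u <- colSums(ranks[y == 1L, , drop = FALSE]) - n1 * (n1 + 1) / 2
  tie_term <- apply(x, 2L, function(col) {
    if (anyDuplicated(col) == 0L) return(0)
    t <- rle(sort(col))$lengths
    sum(t^3 - t)
  })
  sigma2 <- n1 * n0 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- ifelse(sigma2 > 0, (u - n1 * n0 / 2) / sqrt(sigma2), 0)
  p <- ifelse(sigma2 > 0, 2 * stats::pnorm(-abs(z)), 1)
  pmin(p, 1)
}

#' Select features by univariate Mann-Whitney U test
#'
#' Keeps every feature whose two-sided Mann-Whitney U p-value (midrank
#' statistic, tie-corrected normal approximation, unadjusted) is below
#' `alpha`. A constant feature is assigned p = 1 and never selected. If no
#' feature passes, all features are returned with `fallback_used = TRUE`.
#'
#' @param table a [feature_table].
#' @param ref labels: a [reference_vector] aligned to `table` or a 0/1 vector.
#' @param alpha significance threshold (default 0.05, unadjusted).
#' @return a `selection_result` with per-feature p-values in `scores`.
#' @export
select_mannwhitney <- function(table, ref, alpha = 0.05) {
  y <- as_labels(ref, table)
  if (min(table(y)) < 2) stop_refnoise("each class needs >= 2 samples")
  p <- mw_pvalues(table$values, y)
  names(p) <- table$feature_names
  selected <- table$feature_names[p < alpha]
  fallback <- length(selected) == 0
  if (fallback) selected <- table$feature_names
  selection_result("mannwhitney", selected, p, fallback)
}

# Stratified fold ids: within each class, samples are shuffled and folds are
# dealt round-robin, so per-fold class counts differ by at most one.
stratified_folds <- function(y, k, seed = 1L) {
  k <- as.integer(k)
  folds <- integer(length(y))
  with_seed(as.integer(seed), {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# z-score a matrix; returns the transformed matrix plus the training
# statistics so hold-out data can be transformed identically.
zscore_fit <- function(x) {
  center <- colMeans(x)
  scale <- safe_scale(apply(x, 2L, stats::sd))
  list(x = sweep(sweep(x, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

zscore_apply <- function(x, center, scale) {
  sweep(sweep(x, 2L, center), 2L, scale, "/")
}

#' Select features by L1-penalized logistic regression
#'
#' Fits a lasso-penalized logistic model on z-scored features and keeps the
#' features with nonzero coefficients at the penalty chosen by stratified
#' cross-validation (binomial deviance criterion). If the chosen model is
#' empty (intercept only), all features are returned with
#' `fallback_used = TRUE` — the behaviour that produces a stability
#' coefficient of 1 when heavy label noise defeats the selector.
#'
#' @param table a [feature_table].
#' @param ref labels aligned to `table`.
#' @param folds cross-validation folds for the penalty path (reduced to the
#'   minority-class count, floor 3, if the minority class is smaller).
#' @param seed integer seed controlling the fold assignment.
#' @param lambda optional fixed penalty; skips cross-validation when given.
#' @return a `selection_result` with absolute coefficient magnitudes in
#'   `scores` (0 for unselected features).
#' @export
select_lasso <- function(table, ref, folds = 10L, seed = 1L, lambda = NULL) {
  y <- as_labels(ref, table)
  z <- zscore_fit(table$values)
  if (is.null(lambda)) {
    k <- max(3L, min(as.integer(folds), min(table(y))))
    foldid <- stratified_folds(y, k, seed = seed)
    cv <- glmnet::cv.glmnet(z$x, y, family = "binomial", alpha = 1,
                            foldid = foldid, type.measure = "deviance",
                            standardize = FALSE, nlambda = 50,
                            lambda.min.ratio = 0.01)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(z$x, y, family = "binomial", alpha = 1,
                          standardize = FALSE)
  }
  beta <- as.numeric(stats::coef(fit, s = lambda))[-1]  # drop intercept
  names(beta) <- table$feature_names
  selected <- table$feature_names[beta != 0]
  fallback <- length(selected) == 0
  if (fallback) selected <- table$feature_names
  selection_result("lasso", selected, abs(beta), fallback)
}

# Absolute ridge-logistic coefficients on (already z-scored) x: the RFE base
# ranking. Fixed small penalty keeps the fit defined when p > n.
ridge_importance <- function(x, y, lambda = 0.01) {
  if (ncol(x) == 1L) return(1)  # glmnet needs >= 2 columns; ranking is moot
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = c(100, 10, 1, 0.1, lambda),
                        standardize = FALSE)
  abs(as.numeric(stats::coef(fit, s = lambda))[-1])
}

#' Select features by recursive feature elimination
#'
#' Repeatedly fits an L2-penalized logistic model on z-scored features and
#' removes the lowest-|coefficient| features until `n_target` remain. While
#' more than `2 * n_target` features survive, `max(step, floor(p_now / 50))`
#' features are dropped per round (keeps the method tractable at several
#' thousand features); after that, `step` at a time. Ties in importance are
#' broken by feature order. The elimination order is recorded in `scores`
#' (larger = survived longer).
#'
#' @param table a [feature_table].
#' @param ref labels aligned to `table`.
#' @param n_target number of features to retain (>= 1).
#' @param step features removed per fine-stage round (default 1).
#' @return a `selection_result`.
#' @export
select_rfe <- function(table, ref, n_target, step = 1L) {
  y <- as_labels(ref, table)
  p <- n_features(table)
  if (n_target < 1 || n_target > p) {
    stop_refnoise("n_target must be in [1, ", p, "]")
  }
  z <- zscore_fit(table$values)
  remaining <- seq_len(p)
  rank_out <- numeric(p)  # elimination order: 1 = first eliminated
  names(rank_out) <- table$feature_names
  out_counter <- 0L
  while (length(remaining) > n_target) {
    imp <- ridge_importance(z$x[, remaining, drop = FALSE], y)
    n_now <- length(remaining)
    drop_n <- if (n_now > 2L * n_target) {
      max(as.integer(step), n_now %/% 50L)
    } else {
      as.integer(step)
    }
    drop_n <- min(drop_n, n_now - n_target)
    ord <- order(imp, seq_along(imp))  # ascending importance, ties by order
    drop_idx <- remaining[ord[seq_len(drop_n)]]
    rank_out[drop_idx] <- out_counter + seq_len(drop_n)
    out_counter <- out_counter + drop_n
    remaining <- setdiff(remaining, drop_idx)
  }
  # survivors ranked above everything eliminated, ordered by final importance
  final_imp <- ridge_importance(z$x[, remaining, drop = FALSE], y)
  rank_out[remaining] <- out_counter + rank(final_imp, ties.method = "first")
  selection_result("rfe", table$feature_names[sort(remaining)], rank_out)
}

# --- mRMR -------------------------------------------------------------------

# Equal-frequency discretization into B bins; ties are split by original
# order (ties.method = "first") so the binning is deterministic.
discretize_ef <- function(x, bins) {
  n <- length(x)
  as.integer(ceiling(rank(x, ties.method = "first") * bins / n))
}

# Plug-in mutual information (natural log) between two discrete vectors
# coded 1..na and 1..nb.
mi_disc <- function(a, b, na, nb) {
  n <- length(a)
  joint <- tabulate((a - 1L) * nb + b, nbins = na * nb) / n
  pa <- tabulate(a, nbins = na) / n
  pb <- tabulate(b, nbins = nb) / n
  # product marginals in the same layout as joint (b fastest within a)
  pp <- rep(pa, each = nb) * rep(pb, times = na)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / pp[nz]))
}

#' Select features by minimum-redundancy maximum-relevance (mRMR)
#'
#' Greedy forward selection under the MID (difference) criterion: at each
#' step the feature maximizing `I(f; y) - mean_s I(f; s)` over the features
#' `s` already selected is added; the first pick is the most relevant
#' feature. Mutual information is the plug-in estimate on features
#' discretized into `ceiling(sqrt(n))` equal-frequency bins (natural log).
#' Ties are broken by feature order, so the procedure is deterministic.
#'
#' @param table a [feature_table].
#' @param ref labels aligned to `table`.
#' @param n_target number of features to select (>= 1; capped at p).
#' @return a `selection_result`; `selected` is in pick order and `scores`
#'   holds the relevance `I(f; y)` of every candidate.
#' @export
select_mrmr <- function(table, ref, n_target) {
  y <- as_labels(ref, table)
  n <- n_samples(table)
  p <- n_features(table)
  if (n_target < 1) stop_refnoise("n_target must be >= 1")
  n_target <- min(as.integer(n_target), p)
  bins <- as.integer(ceiling(sqrt(n)))
  disc <- apply(table$values, 2L, discretize_ef, bins = bins)
  yd <- y + 1L
  relevance <- vapply(seq_len(p), function(j) mi_disc(disc[, j], yd, bins, 2L),
                      numeric(1))
  names(relevance) <- table$feature_names
  selected_idx <- integer(0)
  redundancy_sum <- numeric(p)
  candidates <- rep(TRUE, p)
  for (step in seq_len(n_target)) {
    if (step == 1L) {
      score <- relevance
    } else {
      score <- relevance - redundancy_sum / length(selected_idx)
    }
    score[!candidates] <- -Inf
    pick <- which.max(score)  # first index wins ties
    selected_idx <- c(selected_idx, pick)
    candidates[pick] <- FALSE
    if (step < n_target) {
      mi_new <- vapply(seq_len(p), function(j) {
        if (candidates[j]) mi_disc(disc[, j], disc[, pick], bins, bins) else 0
      }, numeric(1))
      redundancy_sum <- redundancy_sum + mi_new
    }
  }
  selection_result("mrmr", table$feature_names[selected_idx], relevance)
}

#' Dispatch a selector by name
#'
#' Uniform entry point used by the experiment runner: runs one of the four
#' selectors with its module-level parameters.
#'
#' @param table a [feature_table].
#' @param ref labels aligned to `table`.
#' @param method one of `"mannwhitney"`, `"rfe"`, `"lasso"`, `"mrmr"`.
#' @param n_target target subset size for rfe/mrmr.
#' @param alpha Mann-Whitney threshold.
#' @param folds lasso cross-validation folds.
#' @param seed seed for the lasso fold assignment.
#' @return a `selection_result`.
#' @export
select_features <- function(table, ref,
                            method = c("mannwhitney", "rfe", "lasso", "mrmr"),
                            n_target = 30L, alpha = 0.05, folds = 10L,
                            seed = 1L) {
  method <- match.arg(method)
  switch(method,
         mannwhitney = select_mannwhitney(table, ref, alpha = alpha),
         rfe = select_rfe(table, ref, n_target = n_target),
         lasso = select_lasso(table, ref, folds = folds, seed = seed),
         mrmr = select_mrmr(table, ref, n_target = n_target))
}

#' Multi-set Jaccard similarity
#'
#' `|intersection of all sets| / |union of all sets|` over two or more
#' feature-name sets — the stability coefficient computed across all
#' repetitions at a permutation level (1: every repetition selected exactly
#' the same features; 0: no feature common to all). By convention an empty
#' union yields 1 (all sets identically empty).
#'
#' @param sets a list of >= 2 character vectors.
#' @return a number in \[0, 1\].
#' @export
jaccard_multi <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) {
    stop_refnoise("jaccard_multi needs a list of at least 2 sets")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  inter <- Reduce(intersect, sets)
  uni <- Reduce(union, sets)
  if (length(uni) == 0) return(1)
  length(inter) / length(uni)
}

#' Write a selection result to CSV
#'
#' One row per candidate feature: `method`, `feature`, `selected` (0/1),
#' `score`, `fallback_used`.
#'
#' @param result a `selection_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path) {
  feats <- names(result$scores)
  utils::write.csv(
    data.frame(method = result$method, feature = feats,
               selected = as.integer(feats %in% result$selected),
               score = as.numeric(result$scores),
               fallback_used = result$fallback_used),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
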