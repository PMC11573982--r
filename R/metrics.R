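# Performance metrics on the three evaluation surfaces, the closed-form
# expectation for AUC measured against noisy labels, and the across-level
# ANOVA comparison.

#' ROC AUC (midrank form)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counting one half — computed from midranks,
#' which makes it identical to the tie-corrected Mann-Whitney statistic
#' scaled to \[0, 1\].
#'
#' @param scores numeric vector of classifier scores.
#' @param labels 0/1 vector (or [reference_vector]) of the same length.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as_labels(labels)
  if (length(scores) != length(y)) stop_refnoise("length mismatch")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) {
    stop_refnoise("AUC undefined: labels contain a single class")
  }
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Accuracy, sensitivity, specificity at a score cutoff
#'
#' Predictions are `score >= cutoff`. Sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP), accuracy = (TP + TN) / n.
#'
#' @param scores numeric vector of scores.
#' @param labels 0/1 vector of the same length.
#' @param cutoff decision threshold (default 0.5).
#' @return named numeric vector `c(accuracy, sensitivity, specificity)`.
#' @export
confusion_metrics <- function(scores, labels, cutoff = 0.5) {
  y <- as_labels(labels)
  if (length(scores) != length(y)) stop_refnoise("length mismatch")
  if (length(unique(y)) < 2) {
    stop_refnoise("confusion metrics undefined: single class")
  }
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  c(accuracy = (tp + tn) / length(y),
    sensitivity = tp / sum(y == 1L),
    specificity = tn / sum(y == 0L))
}

#' Expected AUC against balance-preserving noisy labels
#'
#' Closed form for the AUC observed when scores whose true-label AUC is `A`
#' are evaluated against labels permuted at a given level by the
#' balance-preserving flip rule. With per-class flip counts `k_pos`, `k_neg`
#' (same odd-count rule as [permute_reference()]), the noisy-positive group
#' is a mixture of `n_pos - k_pos` true positives and `k_neg` true
#' negatives (weights `w_pp`, `w_pn`) and the noisy-negative group of
#' `n_neg - k_neg` true negatives and `k_pos` true positives (`w_nn`,
#' `w_np`); a positive-negative comparison then wins with probability `A`
#' on a true-positive/true-negative pair, `1 - A` on the reversed pair, and
#' 1/2 within a class (ties assumed negligible):
#' `w_pp * w_nn * A + w_pn * w_np * (1 - A) + (w_pp * w_np + w_pn * w_nn) / 2`.
#'
#' @param true_auc AUC of the scores against true labels, in \[0.5, 1\].
#' @param level flip fraction in \[0, 0.5\].
#' @param prevalence positive-class fraction.
#' @param n number of samples the flips are computed on.
#' @return expected AUC against the permuted labels.
#' @export
expected_noisy_auc <- function(true_auc, level, prevalence, n) {
  if (true_auc < 0.5 || true_auc > 1) {
    stop_refnoise("true_auc must lie in [0.5, 1]")
  }
  if (level < 0 || level > 0.5) stop_refnoise("level must lie in [0, 0.5]")
  n_pos <- round_half_up(prevalence * n)
  n_neg <- n - n_pos
  k <- round_half_up(level * n)
  quota <- flip_quota(n_pos, n_neg, k)
  k_pos <- quota[["k_pos"]]; k_neg <- quota[["k_neg"]]
  w_pp <- (n_pos - k_pos) / (n_pos - k_pos + k_neg)
  w_pn <- k_neg / (n_pos - k_pos + k_neg)
  w_nn <- (n_neg - k_neg) / (n_neg - k_neg + k_pos)
  w_np <- k_pos / (n_neg - k_neg + k_pos)
  w_pp * w_nn * true_auc + w_pn * w_np * (1 - true_auc) +
    (w_pp * w_np + w_pn * w_nn) * 0.5
}

#' Compare a metric across permutation levels
#'
#' One-way fixed-effects ANOVA of a metric across levels (repetitions as
#' replicates), followed by all-pairs t comparisons with Bonferroni
#' adjustment (`adjusted p = min(1, raw p * number of pairs)`). If the
#' metric is constant everywhere the comparison is vacuous: F = 0 and every
#' p-value is 1.
#'
#' @param records data.frame with columns `level`, `repetition` and the
#'   metric column (rows for one pipeline and one evaluation surface).
#' @param metric name of the metric column (default `"auc"`).
#' @param alpha significance threshold for the `significant` flag.
#' @return an object of class `level_comparison`: `metric`, `anova_F`,
#'   `anova_p`, `pairwise` (matrix of Bonferroni-adjusted p-values),
#'   `n_comparisons`, `significant`.
#' @export
compare_levels <- function(records, metric = "auc", alpha = 0.05) {
  if (!metric %in% names(records)) {
    stop_refnoise("no column '", metric, "' in records")
  }
  value <- records[[metric]]
  lev <- factor(records$level)
  if (nlevels(lev) < 2) stop_refnoise("need >= 2 levels to compare")
  if (min(table(lev)) < 2) {
    stop_refnoise("need >= 2 repetitions per level")
  }
  n_pairs <- choose(nlevels(lev), 2)
  if (stats::var(value) == 0) {
    pw <- matrix(1, nlevels(lev) - 1, nlevels(lev) - 1)
    out <- list(metric = metric, anova_F = 0, anova_p = 1, pairwise = pw,
                n_comparisons = n_pairs, significant = FALSE)
    return(structure(out, class = "level_comparison"))
  }
  fit <- stats::aov(value ~ lev)
  s <- summary(fit)[[1]]
  pw <- stats::pairwise.t.test(value, lev, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)$p.value
  structure(list(metric = metric, anova_F = s[["F value"]][1],
                 anova_p = s[["Pr(>F)"]][1], pairwise = pw,
                 n_comparisons = n_pairs,
                 significant = s[["Pr(>F)"]][1] < alpha),
            class = "level_comparison")
}

#' @export
print.level_comparison <- function(x, ...) {
  cat(sprintf("<level_comparison> %s: F = %.3f, p = %.4g (%d pairwise, Bonferroni)\n",
              x$metric, x$anova_F, x$anova_p, x$n_comparisons))
  invisible(x)
}

# One metric row: AUC + confusion metrics of scores against labels.
metric_row <- function(scores, labels, cutoff) {
  cm <- confusion_metrics(scores, labels, cutoff)
  data.frame(auc = roc_auc(scores, labels),
             accuracy = unname(cm["accuracy"]),
             sensitivity = unname(cm["sensitivity"]),
             specificity = unname(cm["specificity"]))
}
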