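# Balance-preserving random label inversion: the clinical-reference
# uncertainty simulation. A permutation level L flips round_half_up(L * n)
# labels, split as evenly as possible between the two classes so that
# prevalence moves by at most one sample.

#' Define a permutation plan
#'
#' The full simulation grid: which permutation levels to run and how many
#' independently-seeded repetitions at each. The defaults are 11 levels in
#' 5% increments from 0 to 50%, 20 repetitions each.
#'
#' @param levels ordered numeric vector of flip fractions in \[0, 0.5\].
#' @param repetitions repetitions per level.
#' @param master_seed integer; every (level, repetition) cell derives its own
#'   seed from this via [derive_seed()].
#' @return an object of class `permutation_plan`.
#' @export
permutation_plan <- function(levels = seq(0, 0.5, by = 0.05),
                             repetitions = 20L, master_seed = 1L) {
  if (any(levels < 0 | levels > 0.5)) {
    stop_refnoise("permutation levels must lie in [0, 0.5]")
  }
  if (repetitions < 1) stop_refnoise("repetitions must be >= 1")
  structure(list(levels = as.numeric(levels),
                 repetitions = as.integer(repetitions),
                 master_seed = as.integer(master_seed)),
            class = "permutation_plan")
}

#' @export
print.permutation_plan <- function(x, ...) {
  cat(sprintf("<permutation_plan> %d levels (%s) x %d repetitions, seed %d\n",
              length(x$levels),
              paste(format(x$levels, trim = TRUE), collapse = ", "),
              x$repetitions, x$master_seed))
  invisible(x)
}

# Split a total flip count k between the two classes: floor(k/2) in one and
# ceiling(k/2) in the other, with the larger half assigned to the majority
# class (ties to the positive class). If a class cannot supply its quota the
# excess is reassigned to the other class; if both together cannot, error.
# Returns c(k_pos, k_neg). Shared by permute_reference() and
# expected_noisy_auc() so the two never drift apart.
flip_quota <- function(n_pos, n_neg, k) {
  if (k > n_pos + n_neg) stop_refnoise("flip count exceeds sample size")
  if (n_pos >= n_neg) {
    k_pos <- ceiling(k / 2); k_neg <- floor(k / 2)
  } else {
    k_pos <- floor(k / 2); k_neg <- ceiling(k / 2)
  }
  if (k_pos > n_pos) {
    k_neg <- k_neg + (k_pos - n_pos); k_pos <- n_pos
  }
  if (k_neg > n_neg) {
    k_pos <- k_pos + (k_neg - n_neg); k_neg <- n_neg
  }
  if (k_pos > n_pos) {
    stop_refnoise("positive class too small to supply its flip quota (",
                  n_pos, " available, ", k_pos, " required)")
  }
  c(k_pos = k_pos, k_neg = k_neg)
}

#' Permute a reference at a given noise level
#'
#' Flips exactly `round_half_up(level * n)` labels, chosen uniformly without
#' replacement within each class, with per-class flip counts as equal as
#' possible (the odd flip goes to the majority class). The permuted
#' prevalence therefore differs from the original by at most `1/n`.
#'
#' @param ref a [reference_vector].
#' @param level flip fraction in \[0, 0.5\].
#' @param seed integer RNG seed; the permutation is deterministic given it.
#' @param repetition optional repetition index recorded for provenance.
#' @return an object of class `permuted_reference`: `sample_ids`, `labels`
#'   (flipped copy), `level`, `repetition`, `flipped_pos_ids` (originally
#'   positive samples flipped to 0), `flipped_neg_ids` (originally negative
#'   flipped to 1), and `seed`.
#' @export
permute_reference <- function(ref, level, seed = 1L, repetition = NA_integer_) {
  if (level < 0 || level > 0.5) {
    stop_refnoise("permutation level must lie in [0, 0.5], got ", level)
  }
  labels <- ref$labels
  n <- length(labels)
  k <- as.integer(round_half_up(level * n))
  pos_ids <- ref$sample_ids[labels == 1L]
  neg_ids <- ref$sample_ids[labels == 0L]
  if (k == 0L) {
    flip_pos <- character(0); flip_neg <- character(0)
  } else {
    quota <- flip_quota(length(pos_ids), length(neg_ids), k)
    flips <- with_seed(as.integer(seed), {
      list(pos = if (quota[["k_pos"]] > 0) sample(pos_ids, quota[["k_pos"]]) else character(0),
           neg = if (quota[["k_neg"]] > 0) sample(neg_ids, quota[["k_neg"]]) else character(0))
    })
    flip_pos <- flips$pos; flip_neg <- flips$neg
  }
  new_labels <- labels
  new_labels[ref$sample_ids %in% flip_pos] <- 0L
  new_labels[ref$sample_ids %in% flip_neg] <- 1L
  structure(list(sample_ids = ref$sample_ids, labels = new_labels,
                 positive_meaning = ref$positive_meaning,
                 level = level, repetition = as.integer(repetition),
                 flipped_pos_ids = flip_pos, flipped_neg_ids = flip_neg,
                 seed = as.integer(seed)),
            class = c("permuted_reference", "reference_vector"))
}

#' @export
print.permuted_reference <- function(x, ...) {
  cat(sprintf(paste0("<permuted_reference> level %.2f, repetition %s: ",
                     "%d + %d flips on %d samples (prevalence %.3f)\n"),
              x$level, ifelse(is.na(x$repetition), "-", x$repetition),
              length(x$flipped_pos_ids), length(x$flipped_neg_ids),
              length(x$labels), mean(x$labels)))
  invisible(x)
}

#' Generate the full grid of permuted references
#'
#' One [permute_reference()] call per (level, repetition) cell of the plan.
#' Each cell's seed is `derive_seed(master_seed, level_index, repetition)`,
#' so any single cell can be regenerated in isolation. Level-0 cells are all
#' identical to the input by construction.
#'
#' @param ref a [reference_vector] (training labels only — permutation is a
#'   training-set operation).
#' @param plan a [permutation_plan].
#' @return a list of `permuted_reference` objects, named
#'   `"L<level>_r<repetition>"`, ordered level-major.
#' @export
generate_repetitions <- function(ref, plan) {
  if (!inherits(plan, "permutation_plan")) {
    stop_refnoise("plan must be a permutation_plan")
  }
  out <- list()
  for (li in seq_along(plan$levels)) {
    for (ri in seq_len(plan$repetitions)) {
      seed <- derive_seed(plan$master_seed, li, ri)
      perm <- permute_reference(ref, plan$levels[li], seed = seed,
                                repetition = ri)
      out[[sprintf("L%.2f_r%d", plan$levels[li], ri)]] <- perm
    }
  }
  out
}

#' Write permuted references to CSV with a JSON provenance sidecar
#'
#' @param perms a list of `permuted_reference` objects (as returned by
#'   [generate_repetitions()]).
#' @param path output CSV path; columns `sample_id`, `label`, `level`,
#'   `repetition`. Provenance (seed and flipped ids per cell) goes to
#'   `<path>.provenance.json`.
#' @return `path`, invisibly.
#' @export
write_permutations <- function(perms, path) {
  rows <- do.call(rbind, lapply(perms, function(p) {
    data.frame(sample_id = p$sample_ids, label = p$labels,
               level = p$level, repetition = p$repetition)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  prov <- lapply(perms, function(p) {
    list(level = p$level, repetition = p$repetition, seed = p$seed,
         flipped_pos_ids = p$flipped_pos_ids,
         flipped_neg_ids = p$flipped_neg_ids)
  })
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
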