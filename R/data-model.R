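# Typed containers for feature tables and binary references, CSV I/O, and
# the prevalence-preserving train/hold-out split.

#' Construct a feature table
#'
#' A feature table is an n-samples by p-features numeric matrix with unique
#' sample identifiers and unique feature names. All values must be finite;
#' validation happens at construction so downstream code can assume a clean
#' matrix.
#'
#' @param values numeric matrix (samples in rows, features in columns).
#' @param sample_ids character vector of unique row identifiers; defaults to
#'   `rownames(values)`.
#' @param feature_names character vector of unique column names; defaults to
#'   `colnames(values)`.
#' @return an object of class `feature_table` with elements `values`
#'   (the matrix, dimnames set), `sample_ids`, `feature_names`.
#' @export
feature_table <- function(values, sample_ids = rownames(values),
                          feature_names = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop_refnoise("feature table values must be numeric")
  }
  if (is.null(sample_ids) || is.null(feature_names)) {
    stop_refnoise("sample_ids and feature_names are required")
  }
  sample_ids <- as.character(sample_ids)
  feature_names <- as.character(feature_names)
  if (length(sample_ids) != nrow(values)) {
    stop_refnoise("length(sample_ids) must equal nrow(values)")
  }
  if (length(feature_names) != ncol(values)) {
    stop_refnoise("length(feature_names) must equal ncol(values)")
  }
  if (anyDuplicated(sample_ids)) {
    stop_refnoise("duplicate sample ids: ",
                  paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(feature_names)) {
    stop_refnoise("duplicate feature names: ",
                  paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(utils::head(bad, 5), 1, function(ij) {
      paste0("(", sample_ids[ij[1]], ", ", feature_names[ij[2]], ")")
    })
    stop_refnoise("non-finite values at cells: ", paste(cells, collapse = ", "),
                  if (nrow(bad) > 5) sprintf(" and %d more", nrow(bad) - 5) else "")
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(list(values = values, sample_ids = sample_ids,
                 feature_names = feature_names),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features\n",
              length(x$sample_ids), length(x$feature_names)))
  invisible(x)
}

#' Number of samples / features in a feature table
#' @param table a `feature_table`.
#' @return integer count.
#' @export
n_samples <- function(table) length(table$sample_ids)

#' @rdname n_samples
#' @export
n_features <- function(table) length(table$feature_names)

#' Read a feature table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row; the first column
#' holds sample identifiers and every remaining column is numeric. Missing
#' or non-numeric cells are an error that names the offending cells.
#'
#' @param path path to a CSV file.
#' @return a validated [feature_table].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    stop_refnoise("feature table CSV needs a sample-id column plus >= 1 feature")
  }
  ids <- as.character(df[[1]])
  feats <- df[-1]
  bad_cells <- character(0)
  for (j in seq_along(feats)) {
    col <- feats[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !is.finite(num))
    for (i in bad) {
      bad_cells <- c(bad_cells,
                     paste0("(row ", ids[i], ", column ", names(feats)[j], ")"))
    }
    feats[[j]] <- num
  }
  if (length(bad_cells) > 0) {
    stop_refnoise("missing or non-numeric cells: ",
                  paste(utils::head(bad_cells, 5), collapse = ", "),
                  if (length(bad_cells) > 5)
                    sprintf(" and %d more", length(bad_cells) - 5) else "")
  }
  feature_table(as.matrix(feats), sample_ids = ids,
                feature_names = names(feats))
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]: first column `sample_id`, one column
#' per feature, comma-separated with a header row.
#'
#' @param table a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = table$sample_ids, table$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a binary reference vector
#'
#' The clinical reference: one label in \{0, 1\} per sample, aligned to a
#' feature table's sample order. Label 1 means the positive class
#' (by default "clinically significant"). Both classes must be present.
#'
#' @param sample_ids character vector of identifiers.
#' @param labels integer/numeric vector of 0/1 labels, same length.
#' @param positive_meaning free-text description of what label 1 means.
#' @return an object of class `reference_vector`.
#' @export
reference_vector <- function(sample_ids, labels,
                             positive_meaning = "clinically significant") {
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != length(labels)) {
    stop_refnoise("sample_ids and labels must have the same length")
  }
  if (anyDuplicated(sample_ids)) {
    stop_refnoise("duplicate sample ids in reference")
  }
  if (!all(labels %in% c(0, 1))) {
    bad <- unique(labels[!labels %in% c(0, 1)])
    stop_refnoise("labels must be 0 or 1; found: ",
                  paste(utils::head(bad, 5), collapse = ", "))
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop_refnoise("single class: reference must contain both 0 and 1 labels")
  }
  structure(list(sample_ids = sample_ids, labels = labels,
                 positive_meaning = positive_meaning),
            class = "reference_vector")
}

#' @export
print.reference_vector <- function(x, ...) {
  cat(sprintf("<reference_vector> %d samples, prevalence %.3f (1 = %s)\n",
              length(x$labels), mean(x$labels), x$positive_meaning))
  invisible(x)
}

#' Proportion of positive labels
#' @param ref a `reference_vector` (or permuted reference).
#' @return fraction of samples labelled 1.
#' @export
prevalence <- function(ref) mean(ref$labels)

#' Read a binary reference from CSV
#'
#' Expects columns `sample_id` and `label` (0/1). If `table` is supplied the
#' reference must cover exactly the table's samples, in the same order.
#'
#' @param path path to a CSV file.
#' @param table optional `feature_table` to align against.
#' @return a validated [reference_vector].
#' @export
read_reference <- function(path, table = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop_refnoise("reference CSV must have columns sample_id, label")
  }
  ref <- reference_vector(df$sample_id, df$label)
  if (!is.null(table)) {
    if (!identical(ref$sample_ids, table$sample_ids)) {
      stop_refnoise("reference sample ids do not match the feature table's ",
                    "ids (same set, same order, required)")
    }
  }
  ref
}

#' Write a reference vector to CSV
#' @param ref a `reference_vector`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  utils::write.csv(data.frame(sample_id = ref$sample_ids, label = ref$labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Align a reference (or permuted reference) to a feature table and return the
# integer 0/1 label vector. Plain 0/1 vectors pass through with a length check.
as_labels <- function(ref, table = NULL) {
  if (inherits(ref, "reference_vector") || inherits(ref, "permuted_reference")) {
    if (!is.null(table) && !identical(ref$sample_ids, table$sample_ids)) {
      stop_refnoise("reference sample ids do not match the feature table")
    }
    return(ref$labels)
  }
  labels <- as.integer(ref)
  if (!is.null(table) && length(labels) != n_samples(table)) {
    stop_refnoise("label vector length does not match the feature table")
  }
  if (!all(labels %in% c(0L, 1L))) stop_refnoise("labels must be 0 or 1")
  labels
}

#' Subset a feature table by sample ids
#' @param table a `feature_table`.
#' @param ids sample identifiers to keep (order preserved as given).
#' @return a `feature_table` restricted to `ids`.
#' @export
subset_table <- function(table, ids) {
  missing <- setdiff(ids, table$sample_ids)
  if (length(missing) > 0) {
    stop_refnoise("unknown sample ids: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  feature_table(table$values[ids, , drop = FALSE], sample_ids = ids,
                feature_names = table$feature_names)
}

#' Subset a reference vector by sample ids
#' @param ref a `reference_vector`.
#' @param ids sample identifiers to keep (order preserved as given).
#' @return a `reference_vector` restricted to `ids`.
#' @export
subset_reference <- function(ref, ids) {
  idx <- match(ids, ref$sample_ids)
  if (anyNA(idx)) {
    stop_refnoise("unknown sample ids: ",
                  paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  }
  reference_vector(ids, ref$labels[idx], ref$positive_meaning)
}

#' Stratified train/hold-out split
#'
#' Partitions samples into a training and a hold-out set at the given ratio,
#' sampling within each label class so that class prevalence is preserved to
#' within one sample. Per-class training counts are `round_half_up(ratio *
#' class size)`; if their sum drifts from `round_half_up(ratio * n)` (a
#' rounding artefact), the majority class absorbs the one-sample difference.
#'
#' @param table a `feature_table`.
#' @param ref a `reference_vector` aligned to `table`.
#' @param ratio fraction of samples assigned to training (default 0.7).
#' @param seed integer RNG seed; the split is deterministic given the seed.
#' @return an object of class `split_assignment` with `train_ids`,
#'   `test_ids`, `ratio`, `seed`.
#' @export
stratified_split <- function(table, ref, ratio = 0.7, seed = 1L) {
  labels <- as_labels(ref, table)
  if (ratio <= 0 || ratio >= 1) stop_refnoise("ratio must be in (0, 1)")
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts < 2)) {
    stop_refnoise("each class needs at least 2 samples to split; class ",
                  names(counts)[counts < 2][1], " has ", min(counts))
  }
  n <- length(labels)
  target_total <- round_half_up(ratio * n)
  take <- round_half_up(ratio * as.numeric(counts))
  # keep at least one sample of each class on both sides
  take <- pmin(pmax(take, 1), as.numeric(counts) - 1)
  names(take) <- names(counts)
  drift <- target_total - sum(take)
  if (drift != 0) {
    maj <- which.max(counts)
    take[maj] <- min(max(take[maj] + drift, 1), counts[maj] - 1)
  }
  train_ids <- with_seed(seed, {
    unlist(lapply(c(0, 1), function(cl) {
      ids <- ref$sample_ids[labels == cl]
      sample(ids, take[as.character(cl)])
    }), use.names = FALSE)
  })
  # preserve the table's sample order within each partition
  train_ids <- table$sample_ids[table$sample_ids %in% train_ids]
  test_ids <- setdiff(table$sample_ids, train_ids)
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> %d train / %d test (ratio %.2f, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$ratio, x$seed))
  invisible(x)
}

#' Write a split assignment to CSV
#' @param split a `split_assignment`.
#' @param path output path; columns `sample_id`, `partition`.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  df <- data.frame(
    sample_id = c(split$train_ids, split$test_ids),
    partition = rep(c("train", "test"),
                    c(length(split$train_ids), length(split$test_ids))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
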