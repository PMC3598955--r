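#' Evaluate classifications against truth labels
#'
#' Accuracy is reported with its explicit counts (`n_correct /
#' n_classified`) over the samples passing the confidence filter. Samples
#' missing from `truth` are excluded and reported via `message()` (real
#' cohorts have partial FISH coverage). With `n_classified = 0` the accuracy
#' is reported as absent (`NA`), never `NaN`.
#'
#' @param results `classification_result` data frame from
#'   [classify_cohort()].
#' @param truth named `HMM`/`NHMM` vector.
#' @param confidence_threshold keep only samples with confidence strictly
#'   greater than this (default 0, i.e. keep all).
#' @return object of class `evaluation_report`: list with `n_samples`,
#'   `n_classified`, `n_correct`, `accuracy`, `confusion` (truth x
#'   predicted), `confidence_threshold`, `per_sample` (prediction,
#'   confidence and truth joined).
#' @export
evaluate <- function(results, truth, confidence_threshold = 0) {
  common <- intersect(results$sample_id, names(truth))
  if (length(common) == 0L) {
    stop("no overlap between classified samples and truth labels", call. = FALSE)
  }
  missing <- setdiff(results$sample_id, names(truth))
  if (length(missing) > 0L) {
    message(sprintf("%d sample(s) lack truth labels and are excluded: %s",
                    length(missing),
                    paste(utils::head(missing, 5L), collapse = ", ")))
  }
  res <- results[results$sample_id %in% common, , drop = FALSE]
  per_sample <- data.frame(res,
                           truth = unname(truth[res$sample_id]),
                           stringsAsFactors = FALSE)
  per_sample$correct <- per_sample$label == per_sample$truth
  kept <- per_sample[per_sample$confidence > confidence_threshold, , drop = FALSE]
  n_classified <- nrow(kept)
  n_correct <- sum(kept$correct)
  confusion <- table(factor(kept$truth, levels = c("HMM", "NHMM")),
                     factor(kept$label, levels = c("HMM", "NHMM")),
                     dnn = c("truth", "predicted"))
  structure(list(n_samples = nrow(per_sample),
                 n_classified = n_classified,
                 n_correct = n_correct,
                 accuracy = if (n_classified > 0L) n_correct / n_classified else NA_real_,
                 confusion = confusion,
                 confidence_threshold = confidence_threshold,
                 per_sample = per_sample),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  if (x$n_classified > 0L) {
    cat(sprintf("Accuracy %.3f (%d/%d) at confidence > %g; %d of %d samples classified\n",
                x$accuracy, x$n_correct, x$n_classified,
                x$confidence_threshold, x$n_classified, x$n_samples))
  } else {
    cat(sprintf("No samples pass confidence > %g (of %d); accuracy undefined\n",
                x$confidence_threshold, x$n_samples))
  }
  print(x$confusion)
  invisible(x)
}

#' Compare the two-feature pipeline with all-DE-gene KNN
#'
#' Runs two classifiers on the same train/test pair: (a) standard KNN in the
#' full differential-gene expression space (each selected gene one
#' coordinate, per-sample standardized values, no TC/NTC compression, no
#' centering), and (b) the two-feature ensemble pipeline, shared verbatim
#' with [classify_cohort()]. Compressing the dosage signal into the two
#' chromosome-set means and centering the cohort makes (b) robust to
#' cross-platform batch structure that degrades (a).
#'
#' @param train_x,train_labels,annotation training cohort (unscaled matrix).
#' @param test_x,test_truth test cohort and its truth labels.
#' @param k neighbors (default 16).
#' @param fdr_threshold differential-expression cutoff (default 0.01).
#' @param ... passed to [train_loocv_ensemble()].
#' @return data frame with one row per mode (`all_de_genes`, `two_feature`):
#'   `accuracy`, `n_correct`, `n_classified`.
#' @export
compare_feature_modes <- function(train_x, train_labels, annotation,
                                  test_x, test_truth, k = 16,
                                  fdr_threshold = 0.01, ...) {
  # mode (a): all differential genes as coordinates
  de <- differential_genes(train_x, train_labels, fdr_threshold = fdr_threshold)
  genes <- intersect(de$selected, rownames(test_x))
  if (length(genes) < 2L) {
    stop("fewer than 2 differential genes shared with the test matrix", call. = FALSE)
  }
  keep <- intersect(colnames(train_x), names(train_labels))
  tr_scaled <- scale_samples(expression_matrix(train_x[, keep, drop = FALSE]))
  te_scaled <- if (is_scaled(test_x)) test_x else scale_samples(test_x)
  tr <- t(tr_scaled[genes, , drop = FALSE])
  te <- t(te_scaled[genes, , drop = FALSE])
  tr_lab <- unname(train_labels[rownames(tr)])
  pred_a <- vapply(seq_len(nrow(te)), function(i) {
    d2 <- rowSums(sweep(tr, 2L, te[i, ], "-")^2)
    .vote_from_d2(d2, tr_lab, k)
  }, character(1L))
  correct_a <- pred_a == unname(test_truth[rownames(te)])

  # mode (b): the product pipeline itself
  ensemble <- train_loocv_ensemble(train_x, train_labels, annotation, k = k,
                                   fdr_threshold = fdr_threshold, ...)
  res_b <- classify_cohort(ensemble, test_x)
  eval_b <- evaluate(res_b, test_truth)

  data.frame(mode = c("all_de_genes", "two_feature"),
             accuracy = c(mean(correct_a), eval_b$accuracy),
             n_correct = c(sum(correct_a), eval_b$n_correct),
             n_classified = c(length(correct_a), eval_b$n_classified),
             stringsAsFactors = FALSE)
}

#' Accuracy of KNN vs weighted KNN on unbalanced test cohorts
#'
#' Depletes the test cohort according to `removal_schedule` (each row gives
#' how many HMM and NHMM samples to remove; the removed samples are the last
#' of their class in column order, deterministically) and classifies each
#' composition with plain KNN and with the optimal-kernel weighted KNN.
#' Because cohort centering depends on class composition, unbalanced cohorts
#' are shifted toward the minority class's side — the regime where the
#' weighted kernel is expected to help.
#'
#' @param train_x,train_labels,annotation training cohort.
#' @param test_x,test_truth test cohort and truth labels.
#' @param removal_schedule data frame with columns `remove_hmm`,
#'   `remove_nhmm`; an empty or NULL schedule evaluates the full test set
#'   once.
#' @param k neighbors (default 16).
#' @param ... passed to [train_loocv_ensemble()].
#' @return data frame with `n_hmm`, `n_nhmm`, `pct_hmm`, `knn_accuracy`,
#'   `kknn_accuracy` per composition.
#' @export
unbalanced_harness <- function(train_x, train_labels, annotation,
                               test_x, test_truth,
                               removal_schedule = NULL, k = 16, ...) {
  if (is.null(removal_schedule) || nrow(removal_schedule) == 0L) {
    removal_schedule <- data.frame(remove_hmm = 0L, remove_nhmm = 0L)
  }
  ensemble <- train_loocv_ensemble(train_x, train_labels, annotation, k = k, ...)
  test_ids <- intersect(colnames(test_x), names(test_truth))
  hmm_ids <- test_ids[test_truth[test_ids] == "HMM"]
  nhmm_ids <- test_ids[test_truth[test_ids] == "NHMM"]
  rows <- lapply(seq_len(nrow(removal_schedule)), function(r) {
    rh <- removal_schedule$remove_hmm[r]
    rn <- removal_schedule$remove_nhmm[r]
    keep_h <- utils::head(hmm_ids, length(hmm_ids) - rh)
    keep_n <- utils::head(nhmm_ids, length(nhmm_ids) - rn)
    if (length(keep_h) < 2L || length(keep_n) < 2L) {
      stop("removal schedule must leave >= 2 samples per class", call. = FALSE)
    }
    sub <- expression_matrix(test_x[, c(keep_h, keep_n), drop = FALSE],
                             scaled = is_scaled(test_x))
    acc <- vapply(c("rectangular", "optimal"), function(kern) {
      evaluate(classify_cohort(ensemble, sub, kernel = kern), test_truth)$accuracy
    }, numeric(1L))
    data.frame(n_hmm = length(keep_h), n_nhmm = length(keep_n),
               pct_hmm = length(keep_h) / (length(keep_h) + length(keep_n)),
               knn_accuracy = acc[["rectangular"]],
               kknn_accuracy = acc[["optimal"]])
  })
  do.call(rbind, rows)
}
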