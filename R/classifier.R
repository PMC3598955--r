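#' K-nearest-neighbor prediction in the two-feature plane
#'
#' Classifies a query point by majority label among its `k` nearest training
#' points under the Euclidean metric, with fully deterministic tie handling:
#' equidistant neighbors at the k-th rank are included by stable order
#' (distance, then training-point index, never expanding beyond `k`), and a
#' tied vote is resolved to the label of the single nearest neighbor among
#' the `k`. Determinism matters because the ensemble reuses each prediction
#' verbatim; random tie-breaking would make runs irreproducible.
#'
#' @param query numeric vector of length 2 (tc_mean, ntc_mean), or a matrix
#'   of query rows.
#' @param points numeric matrix of training points (n x 2).
#' @param labels character vector of training labels (`HMM`/`NHMM`).
#' @param k number of neighbors, `1 <= k <= nrow(points)`.
#' @return character vector of predicted labels, one per query row.
#' @export
knn_predict <- function(query, points, labels, k) {
  kknn_predict(query, points, labels, k, kernel = "rectangular")
}

# Rank-based weights of the "optimal" weighted-KNN kernel.
# Samworth, R. J. (2012) "Optimal weighted nearest neighbour classifiers",
# Annals of Statistics 40(5):2733-2763; the same weights are used by the
# kknn package's 'optimal' kernel. d is the feature-space dimension.
.optimal_kernel_weights <- function(k, d = 2) {
  i <- seq_len(k)
  (1 + d / 2 - d / (2 * k^(2 / d)) * (i^(1 + 2 / d) - (i - 1)^(1 + 2 / d))) / k
}

#' Weighted k-nearest-neighbor prediction
#'
#' Like [knn_predict()] but with kernel-weighted votes. `"rectangular"` is
#' uniform weighting and reduces exactly to plain KNN; `"optimal"` weights
#' the i-th nearest neighbor by the rank-based optimal-kernel scheme of the
#' weighted-KNN literature (see `.optimal_kernel_weights` in the source),
#' which down-weights far neighbors and helps when class sizes are
#' unbalanced. Ties in the weighted vote resolve to the nearest neighbor's
#' label, as in plain KNN.
#'
#' @inheritParams knn_predict
#' @param kernel `"rectangular"` or `"optimal"`.
#' @return character vector of predicted labels.
#' @export
kknn_predict <- function(query, points, labels, k,
                         kernel = c("rectangular", "optimal")) {
  valid <- c("rectangular", "optimal")
  if (length(kernel) > 1L) kernel <- kernel[1L]
  if (!kernel %in% valid) {
    stop("unknown kernel '", kernel, "'; valid kernels: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  if (is.null(dim(query))) query <- matrix(query, ncol = 2L)
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > n) {
    stop(sprintf("k = %d exceeds the number of training points (%d)", k, n),
         call. = FALSE)
  }
  if (length(labels) != n) stop("labels must match training points", call. = FALSE)
  w <- if (kernel == "optimal") .optimal_kernel_weights(k) else rep.int(1, k)
  apply(query, 1L, function(q) {
    d2 <- (points[, 1L] - q[1L])^2 + (points[, 2L] - q[2L])^2
    .vote_from_d2(d2, labels, k, w)
  })
}

# Shared voting core: squared distances in, label out. Used by the 2-D
# classifiers and by the all-DE-gene comparison harness so the two paths
# cannot drift apart.
.vote_from_d2 <- function(d2, labels, k, w = rep.int(1, k)) {
  ord <- order(d2, seq_along(d2))[seq_len(k)]
  lab <- labels[ord]
  vote_hmm <- sum(w[lab == "HMM"])
  vote_nhmm <- sum(w[lab == "NHMM"])
  if (vote_hmm > vote_nhmm) "HMM"
  else if (vote_nhmm > vote_hmm) "NHMM"
  else lab[1L]  # tied vote: label of the single nearest neighbor
}

#' Train a leave-one-out KNN model ensemble
#'
#' For each training sample, one model is fit on the remaining n - 1 samples:
#' genes differentially expressed between HMM and NHMM (per-gene t-test, FDR
#' threshold) are split into trisomy-chromosome (TC) and non-trisomy (NTC)
#' sets, the n - 1 samples' (TC mean, NTC mean) features are computed from
#' the per-sample standardized matrix and centered within the fold, and the
#' model stores its gene lists, centered points and labels. External samples
#' are later classified once per model and the majority vote wins.
#'
#' Standardization is per-column, so it is computed once on the full matrix;
#' the t-test runs on the unscaled matrix by default (`de_on_scaled` switches
#' this). A fold whose TC or NTC differential set is empty is recorded as
#' degenerate and excluded from voting; more than `max_degenerate_frac` of
#' degenerate folds is an error.
#'
#' @param x unscaled expression matrix containing all labeled samples.
#' @param labels named `HMM`/`NHMM` vector; at least 4 samples per class (so
#'   every fold retains 2 for the t-test).
#' @param annotation gene-to-chromosome map; matrix genes absent from it are
#'   used for standardization but excluded from features (the exclusion
#'   count is reported via `message()`).
#' @param k neighbors used at prediction time (default 16).
#' @param fdr_threshold differential-expression FDR cutoff (default 0.01).
#' @param variant,adjust_method passed to [differential_genes()].
#' @param trisomy_set from [trisomy_chromosomes()].
#' @param dataset_name recorded in ensemble metadata.
#' @param de_on_scaled run the t-test on the standardized matrix instead of
#'   the unscaled one (default FALSE).
#' @param max_degenerate_frac error threshold for degenerate folds
#'   (default 0.2).
#' @param seed recorded in metadata for provenance (training itself is
#'   deterministic).
#' @return a validated `knn_ensemble`.
#' @export
train_loocv_ensemble <- function(x, labels, annotation, k = 16,
                                 fdr_threshold = 0.01,
                                 variant = c("welch", "pooled"),
                                 adjust_method = c("BH", "BY"),
                                 trisomy_set = trisomy_chromosomes(),
                                 dataset_name = "training",
                                 de_on_scaled = FALSE,
                                 max_degenerate_frac = 0.2,
                                 seed = NA_integer_) {
  variant <- match.arg(variant)
  adjust_method <- match.arg(adjust_method)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (is_scaled(x)) {
    stop("train_loocv_ensemble expects the unscaled matrix", call. = FALSE)
  }
  keep <- intersect(colnames(x), names(labels))
  labels <- labels[keep]
  x <- expression_matrix(x[, keep, drop = FALSE], scaled = FALSE)
  n_hmm <- sum(labels == "HMM"); n_nhmm <- sum(labels == "NHMM")
  if (n_hmm < 4L || n_nhmm < 4L) {
    stop(sprintf("need >= 4 samples per class for leave-one-out training (HMM: %d, NHMM: %d)",
                 n_hmm, n_nhmm), call. = FALSE)
  }
  scaled <- scale_samples(x)
  de_input <- if (isTRUE(de_on_scaled)) scaled else x
  annotated <- intersect(rownames(x), names(annotation))
  n_unannotated <- nrow(x) - length(annotated)
  if (n_unannotated > 0L) {
    message(sprintf("%d of %d genes lack annotation; kept for standardization, excluded from features",
                    n_unannotated, nrow(x)))
  }
  n <- ncol(x)
  models <- vector("list", n)
  for (i in seq_len(n)) {
    de <- differential_genes(de_input[, -i, drop = FALSE], labels[-i],
                             fdr_threshold = fdr_threshold,
                             variant = variant, adjust_method = adjust_method)
    sel <- intersect(de$selected, annotated)
    part <- if (length(sel) > 0L) {
      partition_tc_ntc(sel, annotation, trisomy_set)
    } else {
      list(tc_genes = character(0L), ntc_genes = character(0L))
    }
    if (length(part$tc_genes) == 0L || length(part$ntc_genes) == 0L) {
      models[[i]] <- list(held_out = colnames(x)[i],
                          tc_genes = part$tc_genes,
                          ntc_genes = part$ntc_genes,
                          center = c(0, 0),
                          degenerate = TRUE,
                          points = matrix(numeric(0L), ncol = 2L,
                                          dimnames = list(NULL, c("tc_mean", "ntc_mean"))),
                          labels = character(0L))
      next
    }
    train_scaled <- scaled[, -i, drop = FALSE]
    attr(train_scaled, "scaled") <- TRUE
    ft <- compute_features(train_scaled, part$tc_genes, part$ntc_genes,
                           dataset_name = dataset_name, min_overlap = 0)
    center <- c(mean(ft$tc_mean), mean(ft$ntc_mean))
    ftc <- center_features(ft)
    models[[i]] <- list(held_out = colnames(x)[i],
                        tc_genes = part$tc_genes,
                        ntc_genes = part$ntc_genes,
                        center = center,
                        degenerate = FALSE,
                        points = cbind(tc_mean = ftc$tc_mean,
                                       ntc_mean = ftc$ntc_mean),
                        labels = unname(labels[-i]))
  }
  n_degen <- sum(vapply(models, function(m) m$degenerate, logical(1L)))
  if (n_degen > 0L) {
    message(sprintf("%d of %d folds degenerate (empty TC or NTC differential set)",
                    n_degen, n))
  }
  if (n_degen > max_degenerate_frac * n) {
    stop(sprintf("%d of %d leave-one-out folds are degenerate (> %.0f%%); the cohort carries too little dosage signal at FDR < %g",
                 n_degen, n, 100 * max_degenerate_frac, fdr_threshold),
         call. = FALSE)
  }
  ensemble <- structure(
    list(models = models,
         k = as.integer(k),
         metadata = list(n_training_samples = n,
                         fdr_threshold = fdr_threshold,
                         training_dataset = dataset_name,
                         variant = variant,
                         adjust_method = adjust_method,
                         seed = seed)),
    class = "knn_ensemble")
  validate_ensemble(ensemble)
  ensemble
}

#' Classify a cohort with a leave-one-out ensemble
#'
#' Every sample is classified once per (non-degenerate) model: the model's
#' own TC/NTC gene lists are used to compute the cohort's features from the
#' standardized matrix, the cohort's feature cloud is centered at the origin
#' (removing dataset/platform offsets), and the sample is classified against
#' the model's centered training points with the ensemble's `k`. Votes are
#' pooled per sample; the majority label wins and the confidence score is
#' the winning proportion of votes. A tied vote yields label `NHMM`,
#' confidence 0.5 and `ambiguous = TRUE`.
#'
#' @param ensemble a `knn_ensemble`.
#' @param x expression matrix; scaled input is used as-is, unscaled input is
#'   standardized internally.
#' @param kernel `"rectangular"` (plain KNN, default) or `"optimal"`
#'   (weighted KNN).
#' @param min_overlap fraction of model genes that must be present in the
#'   matrix before a hard warning is raised (default 0.5).
#' @return data frame of class `classification_result` with `sample_id`,
#'   `label`, `confidence`, `votes_hmm`, `votes_nhmm`, `ambiguous`,
#'   `n_models_voting`; the per-model vote matrix is attached as attribute
#'   `votes`.
#' @export
classify_cohort <- function(ensemble, x, kernel = "rectangular",
                            min_overlap = 0.5) {
  validate_ensemble(ensemble)
  scaled <- if (is_scaled(x)) x else scale_samples(x)
  if (ncol(scaled) == 1L) {
    warning("classifying a single-sample cohort: centering degenerates to the origin",
            call. = FALSE)
  }
  voting <- Filter(function(m) !isTRUE(m$degenerate), ensemble$models)
  if (length(voting) == 0L) stop("ensemble has no voting models", call. = FALSE)
  n <- ncol(scaled)
  votes <- matrix(NA_character_, nrow = length(voting), ncol = n,
                  dimnames = list(NULL, colnames(scaled)))
  worst_overlap <- 1
  for (j in seq_along(voting)) {
    m <- voting[[j]]
    ft <- compute_features(scaled, m$tc_genes, m$ntc_genes, min_overlap = 0)
    ov <- attr(ft, "overlap")
    worst_overlap <- min(worst_overlap,
                         ov[["tc"]] / length(m$tc_genes),
                         ov[["ntc"]] / length(m$ntc_genes))
    ftc <- center_features(ft)
    votes[j, ] <- kknn_predict(cbind(ftc$tc_mean, ftc$ntc_mean),
                               m$points, m$labels, ensemble$k, kernel)
  }
  if (worst_overlap < min_overlap) {
    warning(sprintf("gene overlap with model lists as low as %.0f%%; classifications may be unreliable",
                    100 * worst_overlap), call. = FALSE)
  }
  votes_hmm <- colSums(votes == "HMM")
  votes_nhmm <- colSums(votes == "NHMM")
  tied <- votes_hmm == votes_nhmm
  label <- ifelse(votes_hmm > votes_nhmm, "HMM", "NHMM")
  out <- data.frame(
    sample_id = colnames(scaled),
    label = label,
    confidence = pmax(votes_hmm, votes_nhmm) / length(voting),
    votes_hmm = as.integer(votes_hmm),
    votes_nhmm = as.integer(votes_nhmm),
    ambiguous = tied,
    n_models_voting = length(voting),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("classification_result", "data.frame"),
            votes = votes)
}

#' Split classification results by confidence
#'
#' Samples with confidence strictly greater than `threshold` are kept as
#' classified; the rest are returned too — nothing is dropped silently.
#' Withholding low-confidence calls trades coverage for accuracy, because
#' boundary samples (which the ensemble's models disagree on) are the ones
#' most often misclassified.
#'
#' @param results `classification_result` data frame.
#' @param threshold confidence cutoff in `[0.5, 1]` (default 0.9; strict
#'   inequality).
#' @return list with data frames `classified` and `unclassified`.
#' @export
filter_by_confidence <- function(results, threshold = 0.9) {
  if (threshold < 0.5 || threshold > 1) {
    stop("confidence threshold must be in [0.5, 1]", call. = FALSE)
  }
  keep <- results$confidence > threshold
  list(classified = results[keep, , drop = FALSE],
       unclassified = results[!keep, , drop = FALSE])
}

#' Leave-one-out accuracy as a function of k
#'
#' For each k in `k_range`, every training sample is classified by its own
#' leave-one-out model (a single-model vote, not the ensemble): the held-out
#' sample's features are computed with that fold's gene lists and aligned to
#' the fold's training cloud by subtracting the training centroid. Accuracy
#' is the fraction of non-degenerate folds whose prediction matches the
#' given label. This reproduces the within-dataset model-selection curve
#' used to pick the default k = 16.
#'
#' @inheritParams train_loocv_ensemble
#' @param k_range integer vector of k values (default 1:69); values
#'   exceeding the fold training size are skipped with a message.
#' @param ... passed to [train_loocv_ensemble()].
#' @return list with `table` (data frame `k`, `accuracy`, `n_evaluated`) and
#'   `best_k` (smallest k attaining the maximum accuracy).
#' @export
sweep_k <- function(x, labels, annotation, k_range = 1:69, ...) {
  ensemble <- train_loocv_ensemble(x, labels, annotation, ...)
  keep <- intersect(colnames(x), names(labels))
  labels <- labels[keep]
  scaled <- scale_samples(expression_matrix(x[, keep, drop = FALSE]))
  n_train <- ensemble$metadata$n_training_samples - 1L
  k_range <- as.integer(k_range)
  usable <- k_range[k_range <= n_train & k_range >= 1L]
  skipped <- setdiff(k_range, usable)
  if (length(skipped) > 0L) {
    message("skipping k value(s) exceeding fold size: ",
            paste(skipped, collapse = ", "))
  }
  active <- Filter(function(m) !isTRUE(m$degenerate), ensemble$models)
  # query feature of each held-out sample under its own fold's gene lists,
  # aligned by the fold's training centroid
  queries <- t(vapply(active, function(m) {
    c(mean(scaled[intersect(m$tc_genes, rownames(scaled)), m$held_out]),
      mean(scaled[intersect(m$ntc_genes, rownames(scaled)), m$held_out])) - m$center
  }, numeric(2L)))
  truth <- vapply(active, function(m) unname(labels[m$held_out]), character(1L))
  acc <- vapply(usable, function(k) {
    pred <- vapply(seq_along(active), function(i) {
      knn_predict(queries[i, ], active[[i]]$points, active[[i]]$labels, k)
    }, character(1L))
    mean(pred == truth)
  }, numeric(1L))
  tab <- data.frame(k = usable, accuracy = acc, n_evaluated = length(active))
  list(table = tab, best_k = usable[which.max(acc)])
}
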