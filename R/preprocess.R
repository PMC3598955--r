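#' Per-sample standardization of an expression matrix
#'
#' Each sample column is shifted and scaled so that its mean over all genes
#' is 0 and its sample variance (denominator n - 1) is 1. This removes any
#' per-sample affine distortion (x -> a*x + b, a > 0) and is the step that
#' makes the two-feature embedding comparable across array platforms and
#' datasets.
#'
#' @param x unscaled expression matrix with at least 2 genes.
#' @return expression matrix with `scaled = TRUE`; gene and sample ids
#'   unchanged.
#' @export
scale_samples <- function(x) {
  if (is_scaled(x)) stop("matrix is already scaled", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 genes to standardize", call. = FALSE)
  mu <- colMeans(x)
  v <- colSums(sweep(x, 2L, mu, "-")^2) / (nrow(x) - 1L)
  if (any(v == 0)) {
    stop("zero-variance sample column: ",
         paste(colnames(x)[v == 0], collapse = ", "), call. = FALSE)
  }
  out <- sweep(sweep(x, 2L, mu, "-"), 2L, sqrt(v), "/")
  expression_matrix(out, scaled = TRUE)
}

# Vectorized two-sample t statistics, one gene per row.
# Genes with zero variance in both classes get p = 1 by convention.
.row_t_test <- function(x1, x2, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  } else {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2L, length(tt))
  }
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- (v1 == 0 & v2 == 0)
  tt[degenerate] <- 0
  p[degenerate] <- 1
  list(statistic = tt, p_value = p)
}

#' Differential expression between HMM and NHMM by per-gene t-test
#'
#' Performs a two-sided two-sample t-test per gene between the HMM and NHMM
#' columns, adjusts p-values for multiple testing, and selects genes with
#' adjusted p below `fdr_threshold`. The default test is Welch
#' (unequal-variance), the usual R default; `variant = "pooled"` gives the
#' strict equal-variance Student's test. Selection is conventionally run on
#' the unscaled (but normalized, log2) matrix, before per-sample
#' standardization.
#'
#' @param x expression matrix.
#' @param labels named character vector of `HMM`/`NHMM` covering at least the
#'   samples to use; samples absent from `labels` are ignored.
#' @param fdr_threshold adjusted-p cutoff for selection (default 0.01).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param adjust_method `"BH"` (Benjamini-Hochberg, default) or `"BY"`.
#' @return object of class `de_selection`: data frame `table` with per-gene
#'   `statistic`, `p_value`, `adj_p_value`, plus `selected` (gene ids),
#'   `fdr_threshold`.
#' @export
differential_genes <- function(x, labels, fdr_threshold = 0.01,
                               variant = c("welch", "pooled"),
                               adjust_method = c("BH", "BY")) {
  variant <- match.arg(variant)
  adjust_method <- match.arg(adjust_method)
  labels <- labels[intersect(colnames(x), names(labels))]
  hmm <- names(labels)[labels == "HMM"]
  nhmm <- names(labels)[labels == "NHMM"]
  if (length(hmm) < 2L || length(nhmm) < 2L) {
    stop(sprintf("need >= 2 samples per class for the t-test (HMM: %d, NHMM: %d)",
                 length(hmm), length(nhmm)), call. = FALSE)
  }
  res <- .row_t_test(x[, hmm, drop = FALSE], x[, nhmm, drop = FALSE], variant)
  adj <- stats::p.adjust(res$p_value, method = adjust_method)
  tab <- data.frame(gene_id = rownames(x),
                    statistic = res$statistic,
                    p_value = res$p_value,
                    adj_p_value = adj,
                    stringsAsFactors = FALSE)
  # deterministic ordering: p-value, then gene id
  ord <- order(tab$p_value, tab$gene_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 selected = tab$gene_id[tab$adj_p_value < fdr_threshold],
                 fdr_threshold = fdr_threshold,
                 variant = variant,
                 adjust_method = adjust_method),
            class = "de_selection")
}

#' @export
print.de_selection <- function(x, ...) {
  cat(sprintf("Differential expression: %d of %d genes at FDR < %g (%s t, %s)\n",
              length(x$selected), nrow(x$table), x$fdr_threshold,
              x$variant, x$adjust_method))
  invisible(x)
}

#' Partition genes into trisomy- and non-trisomy-chromosome sets
#'
#' Genes on the trisomy chromosomes (by default 3, 5, 7, 9, 11, 15, 19, 21)
#' form the TC set; all other genes - including chromosome 13, X and Y -
#' form the NTC set. The partition is disjoint and exhaustive over the input.
#'
#' @param genes character vector of gene ids, all present in `annotation`.
#' @param annotation named character vector from [gene_annotation()].
#' @param trisomy_set chromosome set from [trisomy_chromosomes()].
#' @return list with character vectors `tc_genes` and `ntc_genes`.
#' @export
partition_tc_ntc <- function(genes, annotation,
                             trisomy_set = trisomy_chromosomes()) {
  genes <- as.character(genes)
  missing <- setdiff(genes, names(annotation))
  if (length(missing) > 0L) {
    stop("gene(s) missing from annotation: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L),
         call. = FALSE)
  }
  chrom <- annotation[genes]
  list(tc_genes = genes[chrom %in% trisomy_set],
       ntc_genes = genes[!(chrom %in% trisomy_set)])
}
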