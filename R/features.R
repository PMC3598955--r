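#' Two-feature dosage embedding of a cohort
#'
#' For each sample, the TC mean is the arithmetic mean of the scaled
#' expression values over the trisomy-chromosome genes in `tc_genes` (after
#' intersecting with the matrix's genes), and the NTC mean likewise over
#' `ntc_genes`. Trisomies inflate the TC mean through the dosage effect, so
#' HMM and NHMM cohorts separate in this 2-D plane.
#'
#' When fewer than `min_overlap` of either gene list is present in the
#' matrix, a warning is raised (the embedding may be unreliable) but
#' computation proceeds; an empty intersection is an error.
#'
#' @param x scaled expression matrix (see [scale_samples()]).
#' @param tc_genes,ntc_genes character vectors of gene ids.
#' @param dataset_name cohort name recorded on the result.
#' @param min_overlap minimum fraction of each gene list that must be present
#'   before a hard warning is raised (default 0.5).
#' @return `feature_table`: data frame with `sample_id`, `tc_mean`,
#'   `ntc_mean`; attributes `centered` (FALSE), `dataset_name`, and
#'   `overlap` (realized intersection sizes).
#' @export
compute_features <- function(x, tc_genes, ntc_genes, dataset_name = "",
                             min_overlap = 0.5) {
  if (!is_scaled(x)) {
    stop("compute_features requires a scaled matrix (run scale_samples first)",
         call. = FALSE)
  }
  tc_in <- intersect(tc_genes, rownames(x))
  ntc_in <- intersect(ntc_genes, rownames(x))
  if (length(tc_in) == 0L) {
    stop(sprintf("0 of %d TC genes present in the matrix", length(tc_genes)),
         call. = FALSE)
  }
  if (length(ntc_in) == 0L) {
    stop(sprintf("0 of %d NTC genes present in the matrix", length(ntc_genes)),
         call. = FALSE)
  }
  if (length(tc_in) < min_overlap * length(tc_genes) ||
      length(ntc_in) < min_overlap * length(ntc_genes)) {
    warning(sprintf(
      "low gene overlap: %d/%d TC and %d/%d NTC model genes present",
      length(tc_in), length(tc_genes), length(ntc_in), length(ntc_genes)),
      call. = FALSE)
  }
  tab <- data.frame(
    sample_id = colnames(x),
    tc_mean = colMeans(x[tc_in, , drop = FALSE]),
    ntc_mean = colMeans(x[ntc_in, , drop = FALSE]),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(tab, class = c("feature_table", "data.frame"),
            centered = FALSE, dataset_name = dataset_name,
            overlap = c(tc = length(tc_in), ntc = length(ntc_in)))
}

#' Center a cohort's feature cloud at the origin
#'
#' Subtracts the across-sample mean from each coordinate, so the cohort's
#' centroid in the (TC mean, NTC mean) plane is (0, 0). This per-dataset
#' translation removes dataset- and platform-specific offsets and is what
#' allows a model trained on one cohort to classify another.
#'
#' Caveat: the shift is estimated from all submitted samples, so cohort
#' composition biases it — a cohort of (say) all-HMM samples would be
#' mis-centered toward the training cohort's class proportions. Centering a
#' single-sample cohort degenerates to placing the sample at the origin.
#'
#' @param table uncentered `feature_table` with at least 1 sample.
#' @return `feature_table` with `centered = TRUE`.
#' @export
center_features <- function(table) {
  if (isTRUE(attr(table, "centered"))) {
    stop("feature table is already centered", call. = FALSE)
  }
  if (nrow(table) < 1L) stop("cannot center an empty feature table", call. = FALSE)
  out <- table
  out$tc_mean <- out$tc_mean - mean(out$tc_mean)
  out$ntc_mean <- out$ntc_mean - mean(out$ntc_mean)
  attr(out, "centered") <- TRUE
  out
}
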