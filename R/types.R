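#' Domain containers for hyperdiploidy classification
#'
#' `hdmm` works with four small data structures: a log2 expression matrix
#' (genes in rows, samples in columns), a gene-to-chromosome annotation, a
#' table of HMM/NHMM subtype labels, and a per-probe copy-number table. All
#' are validated base-R objects (a numeric matrix, named character vectors and
#' a data frame) so they compose with ordinary R tooling.
#'
#' @name hdmm-types
NULL

VALID_CHROMOSOMES <- c(as.character(1:22), "X", "Y")

#' Normalize chromosome names
#'
#' Strips an optional `chr` prefix (case-insensitive) and upper-cases the sex
#' chromosomes, so `"chr3"`, `"Chr3"` and `"3"` all map to `"3"`.
#'
#' @param x character vector of chromosome tokens.
#' @return character vector of normalized names drawn from `1..22`, `X`, `Y`.
#' @export
normalize_chromosome <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- sub("^CHR", "", x)
  bad <- setdiff(unique(x), VALID_CHROMOSOMES)
  if (length(bad) > 0L) {
    stop("invalid chromosome token(s): ", paste(bad, collapse = ", "),
         " (expected 1..22, X or Y, with optional 'chr' prefix)",
         call. = FALSE)
  }
  x
}

#' Construct a validated expression matrix
#'
#' @param values numeric matrix of log2 expression, genes x samples, with
#'   gene ids as rownames and sample ids as colnames.
#' @param scaled logical; whether per-sample standardization (mean 0,
#'   sample variance 1 per column) has already been applied. Checked when
#'   `TRUE`.
#' @return the matrix, with a `scaled` attribute attached.
#' @export
expression_matrix <- function(values, scaled = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression values must be a numeric matrix", call. = FALSE)
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("expression matrix must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g) > 0L) {
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0L) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    idx <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gene_ids[idx[1L]], sample_ids[idx[2L]]), call. = FALSE)
  }
  if (isTRUE(scaled)) {
    mu <- colMeans(values)
    v <- apply(values, 2L, stats::var)
    if (any(abs(mu) >= 1e-9) || any(abs(v - 1) >= 1e-9)) {
      bad <- sample_ids[which(abs(mu) >= 1e-9 | abs(v - 1) >= 1e-9)[1L]]
      stop(sprintf("matrix flagged scaled but sample '%s' is not standardized", bad),
           call. = FALSE)
    }
  }
  attr(values, "scaled") <- isTRUE(scaled)
  values
}

#' Test whether an expression matrix is per-sample standardized
#' @param x expression matrix.
#' @return logical flag (FALSE when the attribute is absent).
#' @export
is_scaled <- function(x) isTRUE(attr(x, "scaled"))

#' Construct a gene-to-chromosome annotation
#'
#' Duplicate rows with the same chromosome collapse silently; duplicates with
#' conflicting chromosomes are an error.
#'
#' @param gene_id character vector of gene ids.
#' @param chromosome character vector of chromosome tokens (with or without
#'   `chr` prefix).
#' @return named character vector: names are gene ids, values normalized
#'   chromosome names.
#' @export
gene_annotation <- function(gene_id, chromosome) {
  gene_id <- as.character(gene_id)
  chromosome <- normalize_chromosome(chromosome)
  if (length(gene_id) != length(chromosome)) {
    stop("gene_id and chromosome must have the same length", call. = FALSE)
  }
  first <- !duplicated(gene_id)
  ref <- stats::setNames(chromosome[first], gene_id[first])
  conflict <- gene_id[chromosome != ref[gene_id]]
  if (length(conflict) > 0L) {
    stop("conflicting chromosome assignments for gene(s): ",
         paste(unique(conflict), collapse = ", "), call. = FALSE)
  }
  ref
}

#' Construct subtype labels
#'
#' @param sample_id character vector of sample ids (unique).
#' @param subtype character vector with values `"HMM"` or `"NHMM"`.
#' @return named character vector of labels.
#' @export
subtype_labels <- function(sample_id, subtype) {
  sample_id <- as.character(sample_id)
  subtype <- as.character(subtype)
  if (length(sample_id) != length(subtype)) {
    stop("sample_id and subtype must have the same length", call. = FALSE)
  }
  dup <- unique(sample_id[duplicated(sample_id)])
  if (length(dup) > 0L) {
    stop("duplicate sample id(s) in labels: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(subtype), c("HMM", "NHMM"))
  if (length(bad) > 0L) {
    stop("invalid subtype label(s): ", paste(bad, collapse = ", "),
         " (expected HMM or NHMM)", call. = FALSE)
  }
  stats::setNames(subtype, sample_id)
}

#' Construct a per-probe copy-number table
#'
#' One row per probe per sample; `copy_number` is on the linear copy scale
#' (2 = diploid).
#'
#' @param sample_id,probe_id,chromosome,position,copy_number column vectors.
#' @return data frame with normalized chromosome names.
#' @export
copy_number_profile <- function(sample_id, probe_id, chromosome, position,
                                copy_number) {
  chromosome <- normalize_chromosome(chromosome)
  copy_number <- as.numeric(copy_number)
  if (any(!is.finite(copy_number)) || any(copy_number < 0)) {
    bad <- as.character(probe_id)[which(!is.finite(copy_number) | copy_number < 0)[1L]]
    stop(sprintf("copy number must be finite and >= 0 (probe '%s')", bad),
         call. = FALSE)
  }
  data.frame(sample_id = as.character(sample_id),
             probe_id = as.character(probe_id),
             chromosome = chromosome,
             position = as.integer(position),
             copy_number = copy_number,
             stringsAsFactors = FALSE)
}

#' The eight recurrent trisomy chromosomes of hyperdiploid myeloma
#'
#' Hyperdiploid multiple myeloma is defined by trisomies of chromosomes 3, 5,
#' 7, 9, 11, 15, 19 and 21. The set is configurable for research use but
#' defaults to exactly these eight.
#'
#' @param chromosomes character vector of autosome names overriding the
#'   default.
#' @return normalized character vector of chromosome names.
#' @export
trisomy_chromosomes <- function(chromosomes = c("3", "5", "7", "9", "11",
                                                "15", "19", "21")) {
  chromosomes <- unique(normalize_chromosome(chromosomes))
  if (any(chromosomes %in% c("X", "Y"))) {
    stop("trisomy chromosome set must be a subset of the autosomes 1..22",
         call. = FALSE)
  }
  chromosomes
}
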