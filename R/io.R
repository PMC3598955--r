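#' Read a gene expression matrix
#'
#' Expression files are tab-separated with genes in rows and samples in
#' columns (this orientation is a contract, not auto-detected). The `tsv`
#' format has a single header row whose first field is `gene_id` followed by
#' sample ids; `gct` expects two extra header lines (version tag and
#' dimensions) before the same layout. Values are log2 expression.
#'
#' Malformed input is rejected, never coerced: duplicate ids and non-numeric
#' or missing cells raise errors naming the offending record.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"gct"`.
#' @return expression matrix (see [expression_matrix()]), `scaled = FALSE`,
#'   row/column order as in the file.
#' @export
read_expression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (format == "gct") {
    if (length(lines) < 3L) stop("gct file too short: ", path, call. = FALSE)
    lines <- lines[-(1:2)]
  }
  if (length(lines) < 2L) stop("expression file has no data rows: ", path, call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  gene_ids <- vapply(rows, `[`, character(1L), 1L)
  n <- length(sample_ids)
  values <- matrix(NA_real_, nrow = length(rows), ncol = n,
                   dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-1L]
    if (length(cells) != n) {
      stop(sprintf("row for gene '%s' has %d value(s), expected %d",
                   gene_ids[i], length(cells), n), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(cells))
    if (any(is.na(v))) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                   gene_ids[i], sample_ids[j]), call. = FALSE)
    }
    values[i, ] <- v
  }
  expression_matrix(values, scaled = FALSE)
}

#' Write an expression matrix to TSV
#'
#' Values are written with full decimal precision (17 significant digits) so
#' a write/read round trip reproduces the matrix exactly on the decimal
#' representation written.
#'
#' @param x expression matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  header <- paste(c("gene_id", colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path, useBytes = FALSE)
  invisible(path)
}

.read_tsv_table <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id` and `chromosome`; chromosome tokens are
#' accepted with or without a `chr` prefix and normalized.
#'
#' @param path file path.
#' @return named character vector (see [gene_annotation()]).
#' @export
read_gene_annotation <- function(path) {
  df <- .read_tsv_table(path, c("gene_id", "chromosome"))
  gene_annotation(df$gene_id, df$chromosome)
}

#' Read subtype labels
#'
#' TSV with columns `sample_id` and `subtype` (values `HMM`/`NHMM`).
#'
#' @param path file path.
#' @return named character vector (see [subtype_labels()]).
#' @export
read_subtype_labels <- function(path) {
  df <- .read_tsv_table(path, c("sample_id", "subtype"))
  subtype_labels(df$sample_id, df$subtype)
}

#' Write subtype labels to TSV
#' @param labels named character vector of `HMM`/`NHMM`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_subtype_labels <- function(labels, path) {
  utils::write.table(data.frame(sample_id = names(labels), subtype = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-probe copy-number table
#'
#' TSV with columns `sample_id`, `probe_id`, `chromosome`, `position`,
#' `copy_number` (linear copy scale, 2 = diploid).
#'
#' @param path file path.
#' @return data frame (see [copy_number_profile()]).
#' @export
read_copy_number <- function(path) {
  df <- .read_tsv_table(path, c("sample_id", "probe_id", "chromosome",
                                "position", "copy_number"))
  cn <- suppressWarnings(as.numeric(df$copy_number))
  if (any(is.na(cn))) {
    bad <- df$probe_id[which(is.na(cn))[1L]]
    stop(sprintf("non-numeric copy number for probe '%s'", bad), call. = FALSE)
  }
  copy_number_profile(df$sample_id, df$probe_id, df$chromosome,
                      df$position, cn)
}

#' Write a copy-number table to TSV
#' @param profile copy-number data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_copy_number <- function(profile, path) {
  out <- profile
  out$copy_number <- sprintf("%.17g", out$copy_number)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ENSEMBLE_SCHEMA_VERSION <- 1L

#' Validate a leave-one-out KNN ensemble
#'
#' Checks the structural invariants: one model per training sample, disjoint
#' TC/NTC gene sets per model, and each model's stored training points
#' centered at (0, 0) to within 1e-9 per coordinate.
#'
#' @param ensemble a `knn_ensemble` object.
#' @return the ensemble, invisibly; errors on violation.
#' @export
validate_ensemble <- function(ensemble) {
  stopifnot(inherits(ensemble, "knn_ensemble"))
  meta <- ensemble$metadata
  if (length(ensemble$models) != meta$n_training_samples) {
    stop(sprintf("ensemble has %d model(s) but metadata claims %d training sample(s)",
                 length(ensemble$models), meta$n_training_samples), call. = FALSE)
  }
  for (m in ensemble$models) {
    shared <- intersect(m$tc_genes, m$ntc_genes)
    if (length(shared) > 0L) {
      stop("model for held-out sample '", m$held_out,
           "' has overlapping TC/NTC gene sets", call. = FALSE)
    }
    if (nrow(m$points) > 0L && any(abs(colMeans(m$points)) >= 1e-9)) {
      stop("model for held-out sample '", m$held_out,
           "' has uncentered training points", call. = FALSE)
    }
    if (nrow(m$points) != length(m$labels)) {
      stop("model for held-out sample '", m$held_out,
           "' has mismatched points/labels", call. = FALSE)
    }
  }
  invisible(ensemble)
}

#' Serialize a KNN ensemble to structured text
#'
#' The on-disk format is JSON with full decimal precision and a
#' `schema_version` field, chosen for inspectability and cross-language
#' portability. [load_ensemble()] refuses files with an unknown schema
#' version.
#'
#' @param ensemble a `knn_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_ensemble <- function(ensemble, path) {
  validate_ensemble(ensemble)
  payload <- list(
    schema_version = ENSEMBLE_SCHEMA_VERSION,
    metadata = ensemble$metadata,
    k = ensemble$k,
    models = lapply(ensemble$models, function(m) {
      list(held_out = m$held_out,
           k = ensemble$k,
           tc_genes = as.list(m$tc_genes),
           ntc_genes = as.list(m$ntc_genes),
           center = as.numeric(m$center),
           degenerate = isTRUE(m$degenerate),
           points = if (nrow(m$points) > 0L) unname(apply(m$points, 1L, as.list, simplify = FALSE)) else list(),
           labels = as.list(m$labels))
    })
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Load a serialized KNN ensemble
#' @param path file written by [save_ensemble()].
#' @return a validated `knn_ensemble`.
#' @export
load_ensemble <- function(path) {
  if (!file.exists(path)) stop("ensemble file not found: ", path, call. = FALSE)
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ver <- payload$schema_version
  if (is.null(ver) || ver != ENSEMBLE_SCHEMA_VERSION) {
    stop(sprintf("unsupported ensemble schema version '%s' (this build reads version %d)",
                 as.character(ver), ENSEMBLE_SCHEMA_VERSION), call. = FALSE)
  }
  models <- lapply(payload$models, function(m) {
    pts <- if (length(m$points) > 0L) {
      do.call(rbind, lapply(m$points, function(p) as.numeric(unlist(p))))
    } else {
      matrix(numeric(0L), ncol = 2L)
    }
    colnames(pts) <- c("tc_mean", "ntc_mean")
    list(held_out = m$held_out,
         tc_genes = as.character(unlist(m$tc_genes)),
         ntc_genes = as.character(unlist(m$ntc_genes)),
         center = as.numeric(unlist(m$center)),
         degenerate = isTRUE(m$degenerate),
         points = pts,
         labels = as.character(unlist(m$labels)))
  })
  ensemble <- structure(list(models = models,
                             k = as.integer(payload$k),
                             metadata = payload$metadata),
                        class = "knn_ensemble")
  ensemble$metadata$n_training_samples <-
    as.integer(ensemble$metadata$n_training_samples)
  validate_ensemble(ensemble)
  ensemble
}

#' @export
print.knn_ensemble <- function(x, ...) {
  n_degen <- sum(vapply(x$models, function(m) isTRUE(m$degenerate), logical(1L)))
  cat(sprintf("Leave-one-out KNN ensemble: %d models (%d degenerate), k = %d\n",
              length(x$models), n_degen, x$k))
  cat(sprintf("  trained on '%s' (n = %d), FDR threshold %g, seed %s\n",
              x$metadata$training_dataset,
              x$metadata$n_training_samples,
              x$metadata$fdr_threshold,
              as.character(x$metadata$seed)))
  invisible(x)
}
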