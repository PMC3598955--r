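#!/usr/bin/env Rscript
# Reproduces the published-cohort analysis when the user supplies the
# processed GEO matrices (not downloaded here; grab the series matrices for
# GSE6477 / GSE19784 / GSE6401 etc., summarize to gene level, log2 scale,
# and export with the package's TSV conventions).
#
# Usage:
#   Rscript scripts/reproduce_geo.R \
#       --train-expression gse6477.tsv --train-labels gse6477_labels.tsv \
#       --annotation refseq_hg19.tsv \
#       --test-expression gse6401.tsv --test-labels gse6401_labels.tsv \
#       --out-dir geo_results
#
# Produces: the leave-one-out accuracy curve over k = 1..69 for the training
# cohort (the within-dataset curve should stay above 0.80 for k > 2), the
# ensemble classification of the test cohort at k = 16, and its accuracy
# with and without the confidence > 0.9 filter.

suppressMessages(library(hdmm))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(`out-dir` = "geo_results")
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  opt[[key]] <- args[i + 1L]
  i <- i + 2L
}
need <- c("train-expression", "train-labels", "annotation")
missing <- setdiff(need, names(opt))
if (length(missing) > 0L) {
  stop("missing required option(s): ", paste0("--", missing, collapse = ", "),
       "\nThis script needs user-supplied GEO matrices; see the header comment.")
}

x <- read_expression(opt$`train-expression`)
labels <- read_subtype_labels(opt$`train-labels`)
annotation <- read_gene_annotation(opt$annotation)
dir.create(opt$`out-dir`, recursive = TRUE, showWarnings = FALSE)

message("k sweep on the training cohort (leave-one-out)...")
sw <- sweep_k(x, labels, annotation, k_range = 1:69)
utils::write.table(sw$table, file.path(opt$`out-dir`, "k_sweep.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("best k (within-dataset): ", sw$best_k)

if (!is.null(opt$`test-expression`)) {
  ens <- train_loocv_ensemble(x, labels, annotation, k = 16)
  save_ensemble(ens, file.path(opt$`out-dir`, "ensemble.json"))
  tx <- read_expression(opt$`test-expression`)
  res <- classify_cohort(ens, tx)
  utils::write.table(res, file.path(opt$`out-dir`, "classifications.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(opt$`test-labels`)) {
    truth <- read_subtype_labels(opt$`test-labels`)
    print(evaluate(res, truth))
    print(evaluate(res, truth, confidence_threshold = 0.9))
  }
}
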