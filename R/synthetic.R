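#' Configuration for the synthetic myeloma cohort simulator
#'
#' The simulator emulates the statistical structure the classifier relies
#' on: two subtypes; an attenuated trisomy dosage shift on the eight trisomy
#' chromosomes in HMM samples; a hemizygous chromosome 13 deletion in most
#' NHMM samples; per-gene Gaussian noise; per-dataset platform distortions
#' (a per-gene additive batch shift plus per-dataset multiplicative scale
#' and global offset — the scalar part is exactly the family per-sample
#' standardization removes, while the per-gene part is what feature
#' centering absorbs); and normalization attenuation of the copy-number
#' signal in hyperdiploid samples. A small fraction of "boundary" samples
#' carry both trisomies and the chr13 deletion; they are labeled HMM (their
#' karyotype is hyperdiploid) and exist to depress classifier confidence.
#'
#' @param n_samples cohort size (default 140).
#' @param prop_hmm proportion of HMM samples (default 0.5).
#' @param genes_per_chromosome genes simulated per chromosome (scalar,
#'   applied to chromosomes 1..22 and X; default 200), or a named vector of
#'   per-chromosome counts.
#' @param dosage_effect trisomy expression shift in log2 units; default
#'   `log2(3/2) * 0.8`, a 3:2 dosage attenuated by 0.8 because real dosage
#'   response is sub-proportional. Set to 0 for null cohorts.
#' @param chr13_effect log2 shift applied to chromosome 13 genes of deletion
#'   carriers (default -0.8).
#' @param chr13_fraction fraction of NHMM samples carrying the deletion
#'   (default 0.8).
#' @param boundary_fraction fraction of all samples carrying both trisomies
#'   and the chr13 deletion (taken from the HMM pool; default 0.05).
#' @param baseline_mean,baseline_sd per-gene baseline log2 mean distribution
#'   (defaults 7 and 1.5).
#' @param noise_sd per-observation Gaussian noise (default 1).
#' @param batch_shift_sd sd of the per-gene additive batch shift (default 0.5).
#' @param batch_scale_range range of the per-dataset multiplicative scale,
#'   drawn uniformly (default `c(0.8, 1.25)`).
#' @param global_shift constant added to every value after the batch
#'   (default 0; useful for invariance tests).
#' @param cn_probes_per_chromosome copy-number probes per chromosome
#'   (default 100).
#' @param cn_noise_sd per-probe copy-number noise (default 0.15).
#' @param cn_attenuation multiplicative attenuation applied to the whole
#'   copy-number profile of trisomy-carrying samples (default 0.87),
#'   emulating per-sample median normalization that pulls hyperdiploid
#'   profiles down (a 3-copy chromosome then reads ~2.6).
#' @param trisomy_set from [trisomy_chromosomes()].
#' @param seed integer seed fixing every draw.
#' @return validated `sim_config` list.
#' @export
simulation_config <- function(n_samples = 140,
                              prop_hmm = 0.5,
                              genes_per_chromosome = 200,
                              dosage_effect = log2(3 / 2) * 0.8,
                              chr13_effect = -0.8,
                              chr13_fraction = 0.8,
                              boundary_fraction = 0.05,
                              baseline_mean = 7,
                              baseline_sd = 1.5,
                              noise_sd = 1,
                              batch_shift_sd = 0.5,
                              batch_scale_range = c(0.8, 1.25),
                              global_shift = 0,
                              cn_probes_per_chromosome = 100,
                              cn_noise_sd = 0.15,
                              cn_attenuation = 0.87,
                              trisomy_set = trisomy_chromosomes(),
                              seed = 1L) {
  chroms <- c(as.character(1:22), "X")
  if (length(genes_per_chromosome) == 1L && is.null(names(genes_per_chromosome))) {
    genes_per_chromosome <- stats::setNames(rep(as.integer(genes_per_chromosome),
                                                length(chroms)), chroms)
  } else {
    missing <- setdiff(chroms, names(genes_per_chromosome))
    if (length(missing) > 0L) {
      stop("genes_per_chromosome lacks counts for: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    genes_per_chromosome <- genes_per_chromosome[chroms]
  }
  cfg <- list(n_samples = as.integer(n_samples), prop_hmm = prop_hmm,
              genes_per_chromosome = genes_per_chromosome,
              dosage_effect = dosage_effect, chr13_effect = chr13_effect,
              chr13_fraction = chr13_fraction,
              boundary_fraction = boundary_fraction,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd, batch_shift_sd = batch_shift_sd,
              batch_scale_range = batch_scale_range,
              global_shift = global_shift,
              cn_probes_per_chromosome = as.integer(cn_probes_per_chromosome),
              cn_noise_sd = cn_noise_sd, cn_attenuation = cn_attenuation,
              trisomy_set = trisomy_set, seed = as.integer(seed))
  for (p in c("prop_hmm", "chr13_fraction", "boundary_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(p, " must be in [0, 1]", call. = FALSE)
    }
  }
  for (p in c("baseline_sd", "noise_sd", "batch_shift_sd", "cn_noise_sd")) {
    if (cfg[[p]] < 0) stop(p, " must be >= 0", call. = FALSE)
  }
  if (length(cfg$batch_scale_range) != 2L || any(cfg$batch_scale_range <= 0) ||
      diff(cfg$batch_scale_range) < 0) {
    stop("batch_scale_range must be an increasing positive pair", call. = FALSE)
  }
  if (cfg$n_samples < 2L) stop("n_samples must be >= 2", call. = FALSE)
  if (cfg$cn_attenuation <= 0) stop("cn_attenuation must be > 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate a paired expression / copy-number cohort
#'
#' Draws a cohort under the generative model described in
#' [simulation_config()]. All randomness comes from `config$seed`, so the
#' same configuration regenerates the cohort bit-identically.
#'
#' @param config a `sim_config`.
#' @param dataset_name cohort name recorded in the output.
#' @return list of class `synthetic_cohort`: `expression` (unscaled log2
#'   matrix), `labels` (planted truth), `copy_number`, `annotation`,
#'   `boundary_samples`, `del13_samples`, `config`, `dataset_name`.
#' @export
simulate_cohort <- function(config, dataset_name = "sim") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- names(config$genes_per_chromosome)
  gene_chrom <- rep(chroms, config$genes_per_chromosome)
  gene_ids <- unlist(lapply(chroms, function(ch) {
    sprintf("g%s_%03d", ch, seq_len(config$genes_per_chromosome[[ch]]))
  }), use.names = FALSE)
  annotation <- gene_annotation(gene_ids, gene_chrom)
  n_genes <- length(gene_ids)
  n <- config$n_samples
  sample_ids <- sprintf("%s_S%03d", dataset_name, seq_len(n))

  n_hmm <- round(n * config$prop_hmm)
  lab <- sample(c(rep("HMM", n_hmm), rep("NHMM", n - n_hmm)))
  labels <- subtype_labels(sample_ids, lab)
  hmm_ids <- sample_ids[lab == "HMM"]
  nhmm_ids <- sample_ids[lab == "NHMM"]
  n_boundary <- min(round(n * config$boundary_fraction), length(hmm_ids))
  boundary <- if (n_boundary > 0L) sample(hmm_ids, n_boundary) else character(0L)
  n_del <- round(config$chr13_fraction * length(nhmm_ids))
  del13_nhmm <- if (n_del > 0L) sample(nhmm_ids, n_del) else character(0L)
  del13 <- c(del13_nhmm, boundary)
  trisomic <- hmm_ids  # every HMM sample (incl. boundary) carries the trisomies

  baseline <- stats::rnorm(n_genes, config$baseline_mean, config$baseline_sd)
  expr <- matrix(stats::rnorm(n_genes * n, 0, config$noise_sd),
                 nrow = n_genes, ncol = n,
                 dimnames = list(gene_ids, sample_ids))
  expr <- expr + baseline
  on_tc <- gene_chrom %in% config$trisomy_set
  on_13 <- gene_chrom == "13"
  expr[on_tc, trisomic] <- expr[on_tc, trisomic] + config$dosage_effect
  if (length(del13) > 0L) {
    expr[on_13, del13] <- expr[on_13, del13] + config$chr13_effect
  }
  batch_shift <- stats::rnorm(n_genes, 0, config$batch_shift_sd)
  batch_scale <- stats::runif(1L, config$batch_scale_range[1L],
                              config$batch_scale_range[2L])
  expr <- batch_scale * expr + batch_shift + config$global_shift

  # copy-number profiles: copy 3 on trisomy chromosomes for HMM, copy 1 on
  # chr13 for deletion carriers, diploid elsewhere; trisomy carriers
  # attenuated globally (normalization emulation), then per-probe noise
  n_probes <- config$cn_probes_per_chromosome
  probe_chrom <- rep(chroms, each = n_probes)
  probe_ids <- paste0("p", probe_chrom, "_", rep(seq_len(n_probes), length(chroms)))
  probe_pos <- rep(seq_len(n_probes) * 100000L, length(chroms))
  p_tc <- probe_chrom %in% config$trisomy_set
  p_13 <- probe_chrom == "13"
  cn_list <- lapply(sample_ids, function(s) {
    cn <- rep(2, length(probe_ids))
    if (s %in% trisomic) cn[p_tc] <- 3
    if (s %in% del13) cn[p_13] <- 1
    if (s %in% trisomic) cn <- cn * config$cn_attenuation
    cn <- cn + stats::rnorm(length(cn), 0, config$cn_noise_sd)
    pmax(cn, 0)
  })
  copy_number <- copy_number_profile(
    sample_id = rep(sample_ids, each = length(probe_ids)),
    probe_id = rep(probe_ids, n),
    chromosome = rep(probe_chrom, n),
    position = rep(probe_pos, n),
    copy_number = unlist(cn_list, use.names = FALSE))

  structure(list(expression = expression_matrix(expr, scaled = FALSE),
                 labels = labels,
                 copy_number = copy_number,
                 annotation = annotation,
                 boundary_samples = boundary,
                 del13_samples = del13,
                 config = config,
                 dataset_name = dataset_name),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic MM cohort '%s': %d samples (%d HMM / %d NHMM, %d boundary), %d genes\n",
              x$dataset_name, ncol(x$expression), sum(x$labels == "HMM"),
              sum(x$labels == "NHMM"), length(x$boundary_samples),
              nrow(x$expression)))
  invisible(x)
}

#' Simulate an independent cohort on a second platform
#'
#' Draws fresh samples from the same label-generating process as `cohort`
#' but with its own per-dataset batch (new per-gene additive shift and
#' multiplicative scale) and, optionally, a random subset of genes removed
#' to emulate platform gene-set mismatch — the cross-dataset scenario the
#' centering adjustment exists for.
#'
#' @param cohort a `synthetic_cohort` to mirror.
#' @param n_samples size of the new cohort (default: same as `cohort`).
#' @param gene_dropout fraction of genes absent from the new platform
#'   (default 0.15).
#' @param batch_shift_sd,batch_scale_range,global_shift batch overrides
#'   (defaults: inherited from `cohort$config`).
#' @param seed seed for the new cohort's draws.
#' @param dataset_name name for the new cohort.
#' @return a `synthetic_cohort`.
#' @export
simulate_second_platform <- function(cohort, n_samples = NULL,
                                     gene_dropout = 0.15,
                                     batch_shift_sd = NULL,
                                     batch_scale_range = NULL,
                                     global_shift = NULL,
                                     seed = cohort$config$seed + 1L,
                                     dataset_name = "sim2") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (gene_dropout < 0 || gene_dropout >= 1) {
    stop("gene_dropout must be in [0, 1)", call. = FALSE)
  }
  cfg <- unclass(cohort$config)
  if (!is.null(n_samples)) cfg$n_samples <- as.integer(n_samples)
  if (!is.null(batch_shift_sd)) cfg$batch_shift_sd <- batch_shift_sd
  if (!is.null(batch_scale_range)) cfg$batch_scale_range <- batch_scale_range
  if (!is.null(global_shift)) cfg$global_shift <- global_shift
  cfg$seed <- as.integer(seed)
  cfg <- do.call(simulation_config, cfg)
  out <- simulate_cohort(cfg, dataset_name = dataset_name)
  if (gene_dropout > 0) {
    keep <- sort(sample(nrow(out$expression),
                        round((1 - gene_dropout) * nrow(out$expression))))
    out$expression <- expression_matrix(out$expression[keep, , drop = FALSE])
  }
  out
}

#' Write a synthetic cohort to TSV files
#'
#' Writes `expression.tsv`, `annotation.tsv`, `labels.tsv`,
#' `copy_number.tsv` and a `provenance.json` (full configuration and seed)
#' into `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("expression.tsv", "annotation.tsv", "labels.tsv",
                            "copy_number.tsv", "provenance.json"))
  write_expression(cohort$expression, paths[1L])
  utils::write.table(data.frame(gene_id = names(cohort$annotation),
                                chromosome = unname(cohort$annotation)),
                     paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  write_subtype_labels(cohort$labels, paths[3L])
  write_copy_number(cohort$copy_number, paths[4L])
  prov <- unclass(cohort$config)
  prov$dataset_name <- cohort$dataset_name
  prov$tool_version <- as.character(utils::packageVersion("hdmm"))
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), paths[5L])
  invisible(paths)
}
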