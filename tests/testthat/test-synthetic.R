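test_that("the same configuration regenerates the cohort bit-identically", {
  cfg <- small_config(seed = 61)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(unclass(a$expression)[, ], unclass(b$expression)[, ])
  expect_identical(a$labels, b$labels)
  expect_identical(a$copy_number, b$copy_number)
  expect_identical(a$boundary_samples, b$boundary_samples)
})

test_that("cohort pieces are mutually consistent", {
  cfg <- simulation_config(n_samples = 30, genes_per_chromosome = 15,
                           cn_probes_per_chromosome = 12, seed = 62)
  co <- simulate_cohort(cfg)
  expect_identical(ncol(co$expression), 30L)
  expect_identical(nrow(co$expression), 15L * 23L)
  expect_identical(sort(names(co$labels)), sort(colnames(co$expression)))
  expect_identical(sort(unique(co$copy_number$sample_id)),
                   sort(colnames(co$expression)))
  expect_setequal(names(co$annotation), rownames(co$expression))
  expect_identical(sum(co$labels == "HMM"), 15L)
  # boundary samples are HMM-labeled trisomy carriers with the deletion
  expect_true(all(co$labels[co$boundary_samples] == "HMM"))
})

test_that("the planted dosage effect has the configured size", {
  cfg <- simulation_config(n_samples = 80, genes_per_chromosome = 40,
                           batch_shift_sd = 0, batch_scale_range = c(1, 1),
                           boundary_fraction = 0, seed = 63)
  co <- simulate_cohort(cfg)
  tc_genes <- names(co$annotation)[co$annotation %in% trisomy_chromosomes()]
  hmm <- names(co$labels)[co$labels == "HMM"]
  nhmm <- names(co$labels)[co$labels == "NHMM"]
  diff_means <- mean(co$expression[tc_genes, hmm]) -
    mean(co$expression[tc_genes, nhmm])
  se <- sqrt(2 / (length(tc_genes) * 40)) # noise sd 1 per observation
  expect_lt(abs(diff_means - cfg$dosage_effect), 3 * se)
})

test_that("a null configuration carries no label signal", {
  cfg <- simulation_config(n_samples = 60, genes_per_chromosome = 30,
                           dosage_effect = 0, chr13_effect = 0,
                           boundary_fraction = 0, batch_shift_sd = 0,
                           batch_scale_range = c(1, 1), seed = 64)
  co <- simulate_cohort(cfg)
  tc_genes <- names(co$annotation)[co$annotation %in% trisomy_chromosomes()]
  hmm <- names(co$labels)[co$labels == "HMM"]
  nhmm <- names(co$labels)[co$labels == "NHMM"]
  diff_means <- mean(co$expression[tc_genes, hmm]) -
    mean(co$expression[tc_genes, nhmm])
  expect_lt(abs(diff_means), 3 * sqrt(2 / (length(tc_genes) * 30)))
})

test_that("copy-number truth calling agrees with the planted labels", {
  co <- simulate_cohort(simulation_config(n_samples = 60,
                                          genes_per_chromosome = 10,
                                          seed = 65))
  for (stat in c("median_ratio", "trisomy_median")) {
    calls <- call_hmm(co$copy_number, stat)
    expect_gte(mean(calls$label == co$labels[calls$sample_id]), 0.98)
  }
  # attenuation emulates normalization: HMM trisomy medians sit near 2.6
  med <- call_hmm(co$copy_number, "trisomy_median")
  hmm_meds <- med$statistic[co$labels[med$sample_id] == "HMM"]
  expect_lt(abs(mean(hmm_meds) - 2.61), 0.05)
})

test_that("a second platform draws fresh samples and drops genes", {
  co <- simulate_cohort(small_config(seed = 66))
  te <- simulate_second_platform(co, n_samples = 10, gene_dropout = 0.15,
                                 seed = 67, dataset_name = "p2")
  expect_identical(ncol(te$expression), 10L)
  expect_identical(nrow(te$expression),
                   as.integer(round(0.85 * nrow(co$expression))))
  expect_true(all(rownames(te$expression) %in% rownames(co$expression)))
  expect_false(any(colnames(te$expression) %in% colnames(co$expression)))

  same <- simulate_second_platform(co, gene_dropout = 0, seed = 68)
  expect_identical(dim(same$expression), dim(co$expression))
})

test_that("a constant platform offset is erased by standardization", {
  co <- simulate_cohort(small_config(seed = 69))
  plain <- simulate_second_platform(co, gene_dropout = 0, seed = 70,
                                    global_shift = 0)
  shifted <- simulate_second_platform(co, gene_dropout = 0, seed = 70,
                                      global_shift = 2)
  expect_equal(unclass(shifted$expression)[, ] - unclass(plain$expression)[, ],
               matrix(2, nrow(plain$expression), ncol(plain$expression),
                      dimnames = dimnames(plain$expression)),
               tolerance = 1e-12)
  s1 <- scale_samples(plain$expression)
  s2 <- scale_samples(shifted$expression)
  expect_lt(max(abs(s1 - s2)), 1e-9)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(prop_hmm = 1.2), "prop_hmm")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(batch_scale_range = c(2, 1)), "increasing")
  expect_error(simulation_config(n_samples = 1), "n_samples")
  expect_error(simulate_second_platform(
    simulate_cohort(small_config()), gene_dropout = 1), "gene_dropout")
})

test_that("cohorts round-trip through their TSV files", {
  co <- simulate_cohort(small_config(n_samples = 8, seed = 71))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(unclass(read_expression(file.path(dir, "expression.tsv")))[, ],
               unclass(co$expression)[, ], tolerance = 0)
  expect_identical(read_subtype_labels(file.path(dir, "labels.tsv")),
                   co$labels)
  ann <- read_gene_annotation(file.path(dir, "annotation.tsv"))
  expect_identical(ann[names(co$annotation)], co$annotation)
  prov <- jsonlite::fromJSON(file.path(dir, "provenance.json"))
  expect_identical(prov$seed, 71L)
})
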