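test_that("KNN handles exact hits, majorities and tie rules deterministically", {
  pts <- cbind(c(0, 1, 2, 3, 4), c(0, 0, 0, 0, 0))
  labs <- c("HMM", "NHMM", "NHMM", "HMM", "HMM")
  expect_identical(knn_predict(c(2, 0), pts, labs, 1), "NHMM")
  expect_identical(knn_predict(c(0, 0), pts[1, , drop = FALSE], "HMM", 1), "HMM")
  expect_identical(knn_predict(c(3.6, 0), pts, labs, 3),
                   oracle_knn(c(3.6, 0), pts, labs, 3))

  # vote tie at k = 2: the single nearest point decides
  tie_pts <- cbind(c(1, -2), c(0, 0))
  expect_identical(knn_predict(c(0, 0), tie_pts, c("HMM", "NHMM"), 2), "HMM")
  expect_identical(knn_predict(c(0, 0), tie_pts, c("NHMM", "HMM"), 2), "NHMM")

  expect_error(knn_predict(c(0, 0), pts, labs, 6), "exceeds")
  expect_error(knn_predict(c(0, 0), pts, labs, 0), "k must be")
})

test_that("KNN agrees with the exhaustive-sort oracle on random fixtures", {
  for (s in 1:200) {
    fx <- random_feature_fixture(n = sample(3:25, 1), seed = s)
    k <- sample(nrow(fx$points), 1)
    expect_identical(knn_predict(fx$query, fx$points, fx$labels, k),
                     oracle_knn(fx$query, fx$points, fx$labels, k))
  }
})

test_that("predictions are invariant to training-point order", {
  for (s in 300:330) {
    fx <- random_feature_fixture(n = 15, seed = s)
    k <- sample(15, 1)
    perm <- sample(15)
    expect_identical(
      knn_predict(fx$query, fx$points, fx$labels, k),
      knn_predict(fx$query, fx$points[perm, ], fx$labels[perm], k))
  }
})

test_that("weighted KNN reduces to plain KNN under the rectangular kernel", {
  for (s in 401:440) {
    fx <- random_feature_fixture(n = 20, seed = s)
    k <- sample(20, 1)
    expect_identical(
      kknn_predict(fx$query, fx$points, fx$labels, k, "rectangular"),
      knn_predict(fx$query, fx$points, fx$labels, k))
  }
})

test_that("the optimal kernel lets a close neighbor outvote two far ones", {
  # hand-computed: k = 3, rank weights (2 - (2i-1)/3)/3 = 5/9, 3/9, 1/9;
  # the single HMM at distance 1 carries 5/9 > 4/9 of the two NHMM
  pts <- cbind(c(1, 10, -10), c(0, 0, 0))
  labs <- c("HMM", "NHMM", "NHMM")
  expect_identical(kknn_predict(c(0, 0), pts, labs, 3, "optimal"), "HMM")
  expect_identical(knn_predict(c(0, 0), pts, labs, 3), "NHMM")

  # k = 1: any kernel is the nearest-neighbor rule
  expect_identical(kknn_predict(c(9, 0), pts, labs, 1, "optimal"), "NHMM")
  expect_identical(kknn_predict(c(9, 0), pts, labs, 1, "rectangular"), "NHMM")

  expect_error(kknn_predict(c(0, 0), pts, labs, 2, "gaussian"),
               "rectangular, optimal")
})

test_that("LOOCV training builds one model per sample with sane structure", {
  co <- simulate_cohort(small_config(n_samples = 8, seed = 2), "toy")
  ens <- suppressMessages(
    train_loocv_ensemble(co$expression, co$labels, co$annotation, k = 3,
                         dataset_name = "toy"))
  expect_s3_class(ens, "knn_ensemble")
  expect_length(ens$models, 8L)
  for (m in ens$models) {
    expect_false(m$degenerate)
    expect_gt(length(m$tc_genes), 0L)
    expect_gt(length(m$ntc_genes), 0L)
    expect_identical(nrow(m$points), 7L)
    expect_lt(max(abs(colMeans(m$points))), 1e-9)
  }
  expect_identical(sort(vapply(ens$models, `[[`, "", "held_out")),
                   sort(colnames(co$expression)))

  lab_bad <- co$labels
  lab_bad[] <- c("HMM", rep("NHMM", 7))
  expect_error(train_loocv_ensemble(co$expression, lab_bad, co$annotation),
               ">= 4 samples per class")
})

test_that("cohort classification recovers planted labels on clean data", {
  co <- simulate_cohort(small_config(n_samples = 24, seed = 3), "tr")
  ens <- suppressMessages(
    train_loocv_ensemble(co$expression, co$labels, co$annotation, k = 5))
  te <- simulate_cohort(small_config(n_samples = 20, seed = 4), "te")
  res <- classify_cohort(ens, te$expression)
  expect_s3_class(res, "classification_result")
  expect_identical(res$votes_hmm + res$votes_nhmm,
                   rep(res$n_models_voting[1], nrow(res)))
  expect_equal(res$confidence,
               pmax(res$votes_hmm, res$votes_nhmm) / res$n_models_voting)
  expect_gte(mean(res$label == te$labels[res$sample_id]), 0.95)
})

test_that("an even ensemble split is an ambiguous NHMM call at confidence 0.5", {
  pts <- cbind(c(1, -1), c(1, -1))
  model <- function(labs) list(held_out = "x", tc_genes = "G1",
                               ntc_genes = "G2", center = c(0, 0),
                               degenerate = FALSE, points = pts, labels = labs)
  ens <- structure(list(models = list(model(c("HMM", "NHMM")),
                                      model(c("NHMM", "HMM"))),
                        k = 1L,
                        metadata = list(n_training_samples = 2L,
                                        fdr_threshold = 0.01,
                                        training_dataset = "fix",
                                        seed = 1L)),
                   class = "knn_ensemble")
  x <- expression_matrix(matrix(c(1, 2), nrow = 2,
                                dimnames = list(c("G1", "G2"), "solo")))
  res <- suppressWarnings(classify_cohort(ens, x))
  expect_identical(res$label, "NHMM")
  expect_equal(res$confidence, 0.5)
  expect_true(res$ambiguous)
  expect_warning(classify_cohort(ens, x), "single-sample")
})

test_that("confidence filtering uses a strict threshold and drops nothing", {
  res <- data.frame(sample_id = c("a", "b", "c"),
                    confidence = c(0.95, 0.9, 0.5))
  sp <- filter_by_confidence(res, 0.9)
  expect_identical(sp$classified$sample_id, "a")
  expect_identical(sp$unclassified$sample_id, c("b", "c"))

  sp5 <- filter_by_confidence(res, 0.5)
  expect_identical(sp5$classified$sample_id, c("a", "b"))
  expect_identical(sp5$unclassified$sample_id, "c")

  empty <- filter_by_confidence(res[0, , drop = FALSE], 0.9)
  expect_identical(nrow(empty$classified) + nrow(empty$unclassified), 0L)
  expect_error(filter_by_confidence(res, 0.2), "0.5")
})

test_that("the k sweep is perfect on separable cohorts and skips oversized k", {
  co <- simulate_cohort(small_config(n_samples = 16, seed = 5), "sw")
  expect_message(
    sw <- sweep_k(co$expression, co$labels, co$annotation, k_range = c(1:7, 40)),
    "skipping")
  expect_true(all(sw$table$accuracy == 1))
  expect_identical(sw$best_k, 1L)
  expect_false(40 %in% sw$table$k)
})

test_that("accuracy grows with the planted dosage effect and is chance at zero", {
  accs <- vapply(c(0, 0.2, 0.4, 0.58), function(delta) {
    per_seed <- vapply(1:4, function(s) {
      cfg <- simulation_config(n_samples = 48, genes_per_chromosome = 40,
                               dosage_effect = delta, chr13_effect = 0,
                               chr13_fraction = 0, boundary_fraction = 0,
                               seed = 7000 + s)
      co <- simulate_cohort(cfg, "tr")
      ens <- suppressMessages(
        train_loocv_ensemble(co$expression, co$labels, co$annotation,
                             k = 16, fdr_threshold = 1))
      te <- simulate_second_platform(co, n_samples = 40, gene_dropout = 0,
                                     seed = 7500 + s)
      res <- classify_cohort(ens, te$expression)
      mean(res$label == te$labels[res$sample_id])
    }, numeric(1))
    mean(per_seed)
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.02))
  expect_lt(abs(accs[1] - 0.5), 3 * sqrt(0.25 / (4 * 40)))
  expect_gt(accs[4], 0.9)
})
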