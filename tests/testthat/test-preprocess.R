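test_that("per-sample standardization centers and unit-scales every column", {
  m <- expression_matrix(matrix(c(1, 2, 3, 5, 5, 8),
                                nrow = 3,
                                dimnames = list(paste0("g", 1:3), c("a", "b"))))
  s <- scale_samples(m)
  expect_true(is_scaled(s))
  expect_equal(unname(s[, "a"]), c(-1, 0, 1), tolerance = 1e-12)

  # standardized input is a fixed point of the transformation
  again <- scale_samples(expression_matrix(unclass(s)[, ]))
  expect_equal(unclass(again)[, ], unclass(s)[, ], tolerance = 1e-12)

  set.seed(7)
  r <- expression_matrix(matrix(rnorm(500, 7, 2), nrow = 50,
                                dimnames = list(paste0("g", 1:50),
                                                paste0("s", 1:10))))
  rs <- scale_samples(r)
  expect_lt(max(abs(colMeans(rs))), 1e-10)
  expect_lt(max(abs(apply(rs, 2, var) - 1)), 1e-10)
})

test_that("zero-variance samples are rejected by name", {
  m <- expression_matrix(matrix(c(1, 2, 3, 4, 4, 4), nrow = 3,
                                dimnames = list(paste0("g", 1:3),
                                                c("ok", "flat"))))
  expect_error(scale_samples(m), "flat")
})

test_that("standardization cancels any per-sample affine corruption", {
  set.seed(11)
  m <- matrix(rnorm(400, 6, 1.5), nrow = 40,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:10)))
  a <- runif(10, 0.5, 3)
  b <- rnorm(10, 0, 5)
  corrupted <- sweep(sweep(m, 2, a, "*"), 2, b, "+")
  s1 <- scale_samples(expression_matrix(m))
  s2 <- scale_samples(expression_matrix(corrupted))
  expect_lt(max(abs(s1 - s2)), 1e-9)
})

test_that("t statistics match the stats::t.test oracle gene by gene", {
  set.seed(3)
  m <- matrix(rnorm(10 * 12), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  m[1, 1:6] <- m[1, 1:6] + 3
  labels <- subtype_labels(paste0("s", 1:12), rep(c("HMM", "NHMM"), each = 6))
  x <- expression_matrix(m)
  for (variant in c("welch", "pooled")) {
    de <- differential_genes(x, labels, variant = variant)
    for (g in c("g1", "g4", "g9")) {
      ref <- t.test(m[g, 1:6], m[g, 7:12], var.equal = (variant == "pooled"))
      row <- de$table[de$table$gene_id == g, ]
      expect_equal(row$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(row$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("selection behaves at the signal extremes", {
  # identical values in both classes: nothing selectable, p = 1 everywhere
  base <- matrix(rep(1:5, 8), nrow = 5,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  labels <- subtype_labels(paste0("s", 1:8), rep(c("HMM", "NHMM"), each = 4))
  de0 <- differential_genes(expression_matrix(base), labels)
  expect_length(de0$selected, 0L)
  expect_true(all(de0$table$p_value == 1))

  # one overwhelming gene among 99 null genes is selected
  set.seed(5)
  m <- matrix(rnorm(100 * 40), nrow = 100,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:40)))
  m["g1", ] <- rnorm(40, 0, 0.1) + rep(c(0, 10), each = 20)
  lab2 <- subtype_labels(paste0("s", 1:40), rep(c("NHMM", "HMM"), each = 20))
  de1 <- differential_genes(expression_matrix(m), lab2)
  expect_true("g1" %in% de1$selected)
  expect_lt(de1$table$p_value[de1$table$gene_id == "g1"], 1e-20)

  # too-small class errors
  lab3 <- subtype_labels(paste0("s", 1:8), c("HMM", rep("NHMM", 7)))
  expect_error(differential_genes(expression_matrix(base), lab3), "HMM: 1")
})

test_that("BH selection equals the step-up definition on random p-values", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(3:20, 1)
    p <- runif(n)^2  # continuous, so the q*i/m boundary is never hit exactly
    q <- sample(c(0.01, 0.05, 0.2), 1)
    sel_adj <- which(p.adjust(p, "BH") < q)
    expect_identical(sel_adj, oracle_bh_select(p, q))
  }
  # adjusted p monotone-consistent with raw p
  set.seed(22)
  p <- runif(50)
  adj <- p.adjust(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("TC/NTC partition is exhaustive, disjoint and configurable", {
  ann <- gene_annotation(c("G1", "G2"), c("chr3", "chr13"))
  part <- partition_tc_ntc(c("G1", "G2"), ann)
  expect_identical(part$tc_genes, "G1")
  expect_identical(part$ntc_genes, "G2")

  # every gene on a trisomy chromosome: NTC empty
  ann9 <- gene_annotation(paste0("g", 1:5), rep("9", 5))
  p9 <- partition_tc_ntc(paste0("g", 1:5), ann9)
  expect_length(p9$ntc_genes, 0L)
  expect_length(p9$tc_genes, 5L)

  # random assignment: sizes add up, sets disjoint
  set.seed(13)
  genes <- paste0("r", 1:1000)
  chroms <- sample(c(as.character(1:22), "X", "Y"), 1000, replace = TRUE)
  annr <- gene_annotation(genes, chroms)
  pr <- partition_tc_ntc(genes, annr)
  expect_identical(length(pr$tc_genes) + length(pr$ntc_genes), 1000L)
  expect_length(intersect(pr$tc_genes, pr$ntc_genes), 0L)

  # the configured set is honored: chr13 becomes TC
  p13 <- partition_tc_ntc(c("G1", "G2"), ann,
                          trisomy_set = trisomy_chromosomes("13"))
  expect_identical(p13$tc_genes, "G2")

  expect_error(partition_tc_ntc(c("G1", "NOPE"), ann), "NOPE")
})
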