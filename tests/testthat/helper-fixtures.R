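# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no binary fixtures.

# small matrix with known values, genes x samples
tiny_expression <- function() {
  m <- matrix(c(1.5, 2.25, 3.125,
                4.0625, 5.5, 6.75),
              nrow = 3, dimnames = list(c("G1", "G2", "G3"), c("S1", "S2")))
  expression_matrix(m)
}

# attach the scaled flag without re-validating (for hand-built feature
# arithmetic examples that are deliberately not standardized)
flag_scaled <- function(m) {
  attr(m, "scaled") <- TRUE
  m
}

# a fast, strongly separated simulated cohort for unit tests
small_config <- function(n_samples = 24, seed = 1, ...) {
  # chr13_fraction = 1 keeps the NHMM class homogeneous: with only a
  # handful of samples per class, a carrier/non-carrier mixture makes the
  # chr13 genes' within-class variance explode and the tiny-cohort t-tests
  # lose the NTC signal entirely
  args <- list(n_samples = n_samples, genes_per_chromosome = 20,
               dosage_effect = 2, chr13_effect = -2, chr13_fraction = 1,
               noise_sd = 0.3, boundary_fraction = 0, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

# idealized copy-number profile: flat copies, no noise
ideal_profile <- function(sample_id = "S1", tc_copy = 3, other_copy = 2,
                          probes_per_chrom = 10) {
  chroms <- c(as.character(1:22), "X")
  tri <- trisomy_chromosomes()
  chrom <- rep(chroms, each = probes_per_chrom)
  copy_number_profile(
    sample_id = sample_id,
    probe_id = paste0("p", seq_along(chrom)),
    chromosome = chrom,
    position = seq_along(chrom),
    copy_number = ifelse(chrom %in% tri, tc_copy, other_copy))
}

# independent exhaustive-distance-sort KNN oracle: explicit loops, shares
# only the documented tie rules (stable order by distance then index; tied
# vote -> nearest neighbor's label)
oracle_knn <- function(query, points, labels, k) {
  d <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    d[i] <- sqrt((points[i, 1] - query[1])^2 + (points[i, 2] - query[2])^2)
  }
  ord <- order(d, seq_along(d))
  lab <- labels[ord[1:k]]
  n_h <- sum(lab == "HMM"); n_n <- sum(lab == "NHMM")
  if (n_h > n_n) "HMM" else if (n_n > n_h) "NHMM" else lab[1]
}

# direct Benjamini-Hochberg selection from the step-up definition
oracle_bh_select <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= q * seq_len(m) / m)
  if (length(ok) == 0) return(integer(0))
  sort(ord[seq_len(max(ok))])
}

random_feature_fixture <- function(n, seed) {
  set.seed(seed)
  list(points = cbind(stats::rnorm(n), stats::rnorm(n)),
       labels = sample(c("HMM", "NHMM"), n, replace = TRUE),
       query = stats::rnorm(2))
}
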