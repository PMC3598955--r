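.single_sample_profile <- function(profile) {
  if ("sample_id" %in% names(profile) &&
      length(unique(profile$sample_id)) > 1L) {
    stop("profile contains multiple samples; use call_hmm() for cohorts",
         call. = FALSE)
  }
  profile
}

.split_trisomy <- function(profile, trisomy_set, per_chromosome) {
  is_tc <- profile$chromosome %in% trisomy_set
  if (per_chromosome) {
    tc <- vapply(split(profile$copy_number[is_tc], profile$chromosome[is_tc]),
                 stats::median, numeric(1L))
    ntc <- vapply(split(profile$copy_number[!is_tc], profile$chromosome[!is_tc]),
                  stats::median, numeric(1L))
    list(tc = unname(tc), ntc = unname(ntc))
  } else {
    list(tc = profile$copy_number[is_tc], ntc = profile$copy_number[!is_tc])
  }
}

#' Trisomy/non-trisomy median copy-number ratio
#'
#' The median copy number over trisomy-chromosome probes divided by the
#' median over all remaining probes. HMM samples, with ~3 copies of the
#' eight trisomy chromosomes against a diploid background, sit near
#' 1.5 (3/2); NHMM samples near 1.0 (2/2). Because it is a ratio, the
#' statistic is invariant to any global positive rescaling of a sample's
#' copy numbers, such as the downward shift that array normalization
#' inflicts on hyperdiploid genomes.
#'
#' Medians pool probes directly, so probe density weights chromosomes as the
#' array does; `per_chromosome = TRUE` instead takes the median of
#' per-chromosome medians.
#'
#' @param profile single-sample copy-number data frame.
#' @param trisomy_set from [trisomy_chromosomes()].
#' @param per_chromosome see above (default FALSE).
#' @return the ratio (even-count medians are the mean of the two central
#'   values, as usual).
#' @export
median_ratio <- function(profile, trisomy_set = trisomy_chromosomes(),
                         per_chromosome = FALSE) {
  profile <- .single_sample_profile(profile)
  g <- .split_trisomy(profile, trisomy_set, per_chromosome)
  if (length(g$tc) == 0L) stop("no probes on trisomy chromosomes", call. = FALSE)
  if (length(g$ntc) == 0L) stop("no probes on non-trisomy chromosomes", call. = FALSE)
  denom <- stats::median(g$ntc)
  if (denom == 0) stop("non-trisomy median copy number is zero", call. = FALSE)
  stats::median(g$tc) / denom
}

#' Median copy number of the trisomy chromosomes
#'
#' Expected near 3 for HMM and 2 for NHMM on a perfectly calibrated array;
#' in practice normalization attenuates hyperdiploid samples (observed HMM
#' peaks near 2.6). Unlike [median_ratio()], this statistic scales linearly
#' with any global rescaling of the sample's copy numbers.
#'
#' @inheritParams median_ratio
#' @return the median copy number over trisomy-chromosome probes.
#' @export
trisomy_median <- function(profile, trisomy_set = trisomy_chromosomes(),
                           per_chromosome = FALSE) {
  profile <- .single_sample_profile(profile)
  g <- .split_trisomy(profile, trisomy_set, per_chromosome)
  if (length(g$tc) == 0L) stop("no probes on trisomy chromosomes", call. = FALSE)
  stats::median(g$tc)
}

#' Call hyperdiploidy status from copy-number profiles
#'
#' Computes the chosen statistic per sample and calls HMM if and only if the
#' statistic is strictly greater than the cutoff. Default cutoffs are the
#' midpoints between the empirical HMM/NHMM peaks: 1.125 for the median
#' ratio and 2.3 for the trisomy median.
#'
#' @param profiles copy-number data frame, one or more samples (grouped by
#'   `sample_id`).
#' @param statistic `"median_ratio"` or `"trisomy_median"`.
#' @param cutoff decision boundary; defaults to 1.125 or 2.3 according to
#'   `statistic`.
#' @param trisomy_set,per_chromosome passed to the statistic.
#' @return data frame with `sample_id`, `statistic_kind`, `statistic`,
#'   `cutoff`, `label`.
#' @export
call_hmm <- function(profiles,
                     statistic = c("median_ratio", "trisomy_median"),
                     cutoff = NULL,
                     trisomy_set = trisomy_chromosomes(),
                     per_chromosome = FALSE) {
  statistic <- match.arg(statistic)
  if (is.null(cutoff)) {
    cutoff <- if (statistic == "median_ratio") 1.125 else 2.3
  }
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  fn <- if (statistic == "median_ratio") median_ratio else trisomy_median
  by_sample <- split(profiles, profiles$sample_id)
  stat <- vapply(by_sample, fn, numeric(1L),
                 trisomy_set = trisomy_set, per_chromosome = per_chromosome)
  out <- data.frame(sample_id = names(by_sample),
                    statistic_kind = statistic,
                    statistic = unname(stat),
                    cutoff = cutoff,
                    label = ifelse(stat > cutoff, "HMM", "NHMM"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count calls flipped by alternative cutoffs
#'
#' Reclassifies the same statistics under each alternative cutoff and counts
#' samples whose label differs from the reference-cutoff call — the
#' mechanism behind checking that the HMM/NHMM boundary is insensitive to
#' its exact placement.
#'
#' @param calls data frame from [call_hmm()].
#' @param cutoffs numeric vector of alternative cutoffs.
#' @return data frame with `cutoff` and `n_flipped`.
#' @export
cutoff_sensitivity <- function(calls, cutoffs) {
  data.frame(cutoff = cutoffs,
             n_flipped = vapply(cutoffs, function(ct) {
               sum(ifelse(calls$statistic > ct, "HMM", "NHMM") != calls$label)
             }, numeric(1L)))
}

#' Suggest a cutoff between two modes of a statistic's distribution
#'
#' Automates the manual "midpoint between the two histogram peaks" choice:
#' fits a two-component univariate Gaussian mixture by EM, deterministically
#' initialized at the 25th/75th percentiles of the data, and returns the
#' midpoint of the two component means. The default workflow still uses the
#' established cutoffs (1.125 ratio, 2.3 median); this is an aid for new
#' platforms.
#'
#' @param statistics numeric vector (>= 4 values), e.g. per-sample median
#'   ratios.
#' @param min_separation minimum distance between component means before the
#'   fit is declared degenerate (default 1e-3); on degeneracy an error
#'   advises choosing the cutoff manually.
#' @param max_iter,tol EM iteration controls.
#' @return list with `cutoff` (midpoint), `means` (sorted component means),
#'   `sds`, `proportions`.
#' @export
suggest_cutoff <- function(statistics, min_separation = 1e-3,
                           max_iter = 500L, tol = 1e-10) {
  x <- as.numeric(statistics)
  if (length(x) < 4L) stop("need >= 4 values to suggest a cutoff", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("all values identical; mixture fit is degenerate - choose a cutoff manually",
         call. = FALSE)
  }
  mu <- unname(stats::quantile(x, c(0.25, 0.75)))
  if (mu[1L] == mu[2L]) mu <- mu + c(-1, 1) * stats::sd(x) / 4
  sigma <- rep(stats::sd(x) / 2, 2L)
  pi_k <- c(0.5, 0.5)
  var_floor <- 1e-12
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    log_d <- cbind(log(pi_k[1L]) + stats::dnorm(x, mu[1L], sigma[1L], log = TRUE),
                   log(pi_k[2L]) + stats::dnorm(x, mu[2L], sigma[2L], log = TRUE))
    m <- pmax(log_d[, 1L], log_d[, 2L])
    log_sum <- m + log(exp(log_d[, 1L] - m) + exp(log_d[, 2L] - m))
    resp <- exp(log_d - log_sum)
    ll <- sum(log_sum)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) break
    pi_k <- nk / length(x)
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(pmax(colSums(resp * (x - rep(mu, each = length(x)))^2) / nk,
                       var_floor))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (abs(mu[2L] - mu[1L]) < min_separation) {
    stop(sprintf("mixture components nearly coincide (means %.4g and %.4g); choose a cutoff manually",
                 mu[1L], mu[2L]), call. = FALSE)
  }
  ord <- order(mu)
  list(cutoff = mean(mu), means = mu[ord], sds = sigma[ord],
       proportions = pi_k[ord])
}
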