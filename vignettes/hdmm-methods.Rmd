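---
title: "Classifying hyperdiploid myeloma from expression dosage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying hyperdiploid myeloma from expression dosage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdmm)
```

## The problem

Multiple myeloma splits into two major aneuploidy subtypes. Hyperdiploid
myeloma (HMM, roughly 55–60% of patients) carries trisomies of eight
recurrent chromosomes — 3, 5, 7, 9, 11, 15, 19 and 21 — and has the better
prognosis. Non-hyperdiploid myeloma (NHMM) lacks the trisomy pattern and
typically carries translocations and a hemizygous chromosome 13 deletion.
Subtype is normally determined by FISH or copy-number arrays, which most
expression-profiling studies do not include. Because a third copy of a
chromosome raises the expression of the genes on it (the dosage effect),
the subtype leaves a readable imprint in an ordinary expression matrix,
and `hdmm` reads it.

## The classifier

Given a gene × sample log2 expression matrix, chromosome annotation and
HMM/NHMM labels for a training cohort:

1. **Per-fold feature selection.** For each training sample, leave it out
   and run a per-gene two-sided t-test (Welch by default) between the HMM
   and NHMM columns of the remaining samples; keep genes with
   Benjamini–Hochberg adjusted p < 0.01. Split the selected genes into
   trisomy-chromosome (TC) and non-trisomy-chromosome (NTC) sets.
2. **Standardization.** Scale every sample column to mean 0 and sample
   variance 1 over all genes. This removes any per-sample affine
   distortion — the family of corruptions that platform differences in
   overall intensity and dynamic range produce.
3. **Two-feature embedding.** For each sample, TC mean and NTC mean are
   the averages of its standardized values over the fold's TC and NTC
   genes. Dosage pushes HMM samples up the TC axis; chromosome 13 deletion
   pulls NHMM carriers down the NTC axis.
4. **Cohort centering.** Each cohort's feature cloud is translated so its
   centroid is the origin, removing residual dataset-level offsets (e.g.
   per-gene batch shifts, which survive per-sample standardization but
   displace the whole cloud by a constant).
5. **Ensemble KNN.** Each left-out-sample model stores its gene lists and
   its centered training points. A new cohort is classified once per model
   (k = 16 nearest neighbors, Euclidean metric in the feature plane); the
   majority label over the ensemble wins, and the confidence score is the
   winning vote fraction. Calls with confidence ≤ 0.9 can be withheld.

A copy-number module provides truth labels where paired aCGH/SNP profiles
exist: a sample is called HMM when the median copy number over
trisomy-chromosome probes divided by the median over the remaining probes
exceeds 1.125, or (median rule) when the trisomy median exceeds 2.3.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 16 | neighbors per KNN vote; the within-dataset and cross-dataset leave-one-out curves are both flat and high around this value, and `sweep_k()` recomputes the curve for any cohort |
| `fdr_threshold` | 0.01 | BH-adjusted p cutoff for per-fold gene selection |
| `test_variant` | `welch` | `pooled` gives the strict equal-variance Student's test; the two rarely disagree on balanced cohorts |
| `trisomy_chromosomes()` | 3, 5, 7, 9, 11, 15, 19, 21 | the defining trisomy set; configurable for research use, and the TC/NTC partition honors any override |
| `confidence_threshold` | 0.9 | strict cutoff for withholding low-confidence calls |
| CN cutoffs | 1.125 / 2.3 | midpoints between the empirical HMM and NHMM peaks of the two copy-number statistics |
| `kernel` | `rectangular` | `optimal` enables rank-weighted (Samworth) neighbor votes, useful for class-unbalanced cohorts |

## The synthetic cohort generator

`simulate_cohort()` draws paired expression and copy-number cohorts with
exactly the structure the classifier assumes: per-gene baselines
N(7, 1.5²) log2 units; observation noise sd 1; a trisomy dosage shift of
`log2(3/2) × 0.8 ≈ 0.47` log2 units on all trisomy-chromosome genes of HMM
samples (the 0.8 attenuation reflects sub-proportional dosage response;
the true attenuation in myeloma is not well quantified, so this is an
assumption, and it is configurable); a −0.8 log2 shift on chromosome 13
genes of 80% of NHMM samples; and 5% "boundary" samples carrying both the
trisomies and the deletion, labeled HMM because their karyotype is
hyperdiploid (the copy-number ratio rule also calls them HMM).

Platform structure enters as a per-dataset batch: a per-gene additive
shift N(0, 0.5²), a per-dataset multiplicative scale in [0.8, 1.25], and
an optional global offset. The scalar parts are exactly the family that
per-sample standardization removes; the per-gene part survives
standardization and is what cohort centering absorbs — so the generator
cleanly separates what each pipeline stage contributes.
`simulate_second_platform()` additionally drops a random 15% of genes to
emulate platform gene-set mismatch.

Copy-number profiles place 100 probes per chromosome (copy 3 on trisomy
chromosomes of HMM, copy 1 on chromosome 13 of deletion carriers, 2
elsewhere, Gaussian probe noise sd 0.15). Profiles of trisomy carriers are
multiplied by 0.87: array normalization forces each sample's overall
signal toward diploid, which pulls a genome with eight trisomies down
(a 3-copy chromosome then reads near 2.6) while leaving diploid-median
NHMM profiles at 2. This is why the ratio statistic (scale-invariant) and
the median statistic (scale-covariant) need different cutoffs, and why
the ratio cutoff sits at 1.125 rather than 1.25.

What the generator does **not** emulate: probe-level array physics,
RMA/normalization artifacts beyond the affine family, translocations
(t(4;14) and friends), focal or arm-level events other than whole-arm
chr13 loss, tumor-purity dilution, and correlated gene-gene noise.
Passing tests therefore demonstrate that the pipeline recovers
ploidy-driven dosage structure under realistic platform distortions — not
that it reaches any particular accuracy on real cohorts.

## Numerical and design choices

- **Which t-test.** The original description says Student's t-test, but
  the R toolchain it sits in defaults to Welch. Welch is the default here,
  with `variant = "pooled"` exposing the strict reading.
- **Selection before scaling.** Differential expression is computed on the
  unscaled (normalized, log2) matrix and standardization happens
  afterwards, matching the narrative order of the original procedure;
  `de_on_scaled = TRUE` lets you test the other order.
- **Degenerate genes and folds.** A gene with zero variance in both
  classes gets p = 1 (never NaN). A fold whose TC or NTC selection is
  empty is recorded as degenerate and excluded from voting; more than 20%
  degenerate folds is an error, because the ensemble no longer means
  anything. Confidence uses the realized number of voting models.
- **Deterministic ties everywhere.** Equidistant neighbors at the k-th
  rank are included by stable (distance, index) order, never expanding
  beyond k; a tied neighbor vote resolves to the single nearest neighbor's
  label; a tied ensemble vote yields NHMM with confidence 0.5 and an
  `ambiguous` flag. The weighted-KNN reference implementation breaks ties
  randomly, which makes runs irreproducible; determinism was chosen
  instead, and order-invariance is property-tested.
- **Per-model features and centering.** A test cohort's features are
  recomputed per ensemble model from that model's own gene lists and
  centered within the test cohort each time, mirroring the per-model
  retrieval the method describes. Each model's stored training points are
  centered within their own n−1 cloud (the original does not say whether
  training was centered once or per fold; self-contained models were
  chosen). For within-dataset leave-one-out evaluation (`sweep_k`), the
  held-out sample is aligned by subtracting the fold's training centroid,
  which is distance-identical to the original uncentered within-dataset
  procedure.
- **Centering caveat.** The cohort shift is estimated from all submitted
  samples, so cohort composition biases it: an all-HMM cohort would be
  mis-centered and roughly half of it misclassified. Iterative
  re-estimation of the HMM proportion is explicitly out of scope.
- **Copy-number medians** pool probes directly (probe density then weighs
  chromosomes as the array does); `per_chromosome = TRUE` computes the
  median of per-chromosome medians instead. The HMM call is strict
  (statistic > cutoff).
- **Cutoff suggestion.** `suggest_cutoff()` automates the "midpoint
  between the two histogram peaks" choice with a two-component Gaussian
  mixture fit by EM, deterministically initialized at the 25th/75th
  percentiles, erroring when the components nearly coincide. The default
  workflow still uses the established cutoffs.
- **Null calibration.** With no planted signal, feature selection at
  FDR < 0.01 correctly selects nothing and training errors out (by
  design). Null experiments therefore run with `fdr_threshold = 1`, which
  keeps every gene and exercises the embedding/KNN stages on pure noise;
  chance-level accuracy there shows the pipeline manufactures no signal.

## Problem sizes

Study-scale checks train on simulated 140-sample cohorts (200 genes per
chromosome, ~4,600 genes) and classify 100-sample second-platform
cohorts; property-style sweeps (dosage-monotonicity, null calibration)
use 48-sample cohorts with 40 genes per chromosome, sizes at which every
stage's behavior is already stable. The ensemble, voting and confidence
arithmetic are identical at any size.

## Known limitations

- Boundary samples (trisomies plus chr13 deletion) sit between the two
  clouds by construction; at the default effect sizes their 16-NN vote is
  usually won by the nearby NHMM-carrier cluster, so they are typically
  misclassified, and they account for essentially all residual error on
  synthetic cohorts. Withholding low-confidence calls mitigates but does
  not eliminate this, and can occasionally drop a correctly classified
  boundary sample.
- The confidence score is a vote proportion over nearly identical
  leave-one-out models, not a calibrated probability.
- Cohorts are assumed to be mostly tumor: the method has no purity model.
- Only two classes are supported; rarer subtypes (tetraploid genomes,
  chromothripsis-driven cases) will be forced into one of them.
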