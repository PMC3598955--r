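# hdmm — expression-based classification of hyperdiploid multiple myeloma

Multiple myeloma divides into two major aneuploidy subtypes with different
prognosis: **hyperdiploid** (HMM), defined by trisomies of chromosomes
3, 5, 7, 9, 11, 15, 19 and 21, and **non-hyperdiploid** (NHMM), typically
carrying translocations and a hemizygous chromosome 13 deletion. Subtype
is usually measured by FISH or copy-number arrays — which most
expression-profiling studies lack. Because an extra chromosome copy raises
the expression of its genes (the dosage effect), the subtype can be
inferred from the expression matrix alone. `hdmm` is for anyone who wants
HMM/NHMM status for expression cohorts: as a covariate in survival models,
for subtype-stratified meta-analysis, or to audit FISH calls against
paired copy-number data.

## The method

For a training cohort with known labels, each leave-one-out fold selects
genes differentially expressed between HMM and NHMM (per-gene Welch t,
Benjamini–Hochberg FDR < 0.01) and splits them into trisomy-chromosome
(TC) and non-trisomy-chromosome (NTC) sets. After standardizing every
sample to mean 0 / variance 1 over all genes, each sample is embedded as

    ( TC mean , NTC mean )  =  ( mean of scaled expression over TC genes ,
                                 mean over NTC genes )

where HMM and NHMM cohorts separate. To classify a new cohort — even from
a different array platform — each fold's model recomputes the embedding
with its own gene lists, translates the cohort's point cloud so its
centroid is the origin (removing dataset offsets), and votes with
k-nearest neighbors (k = 16) against its stored training points. The
majority over all models is the call and the winning vote fraction is its
confidence; calls with confidence ≤ 0.9 can be withheld. A weighted-KNN
variant (rank-based "optimal" kernel) is available for class-unbalanced
cohorts, and a copy-number module calls truth labels from paired
aCGH/SNP profiles via the trisomy/non-trisomy median ratio (HMM iff
ratio > 1.125) or the trisomy median (> 2.3).

## Worked example

The package ships a cohort simulator, so the whole pipeline runs without
external data:

```r
library(hdmm)

cfg   <- simulation_config(n_samples = 140, seed = 7)
train <- simulate_cohort(cfg, dataset_name = "train")
ens   <- train_loocv_ensemble(train$expression, train$labels,
                              train$annotation, dataset_name = "train")
ens
#> Leave-one-out KNN ensemble: 140 models (0 degenerate), k = 16
#>   trained on 'train' (n = 140), FDR threshold 0.01, seed 7

test  <- simulate_second_platform(train, n_samples = 100, seed = 8,
                                  dataset_name = "newplatform")
calls <- classify_cohort(ens, test$expression)
head(calls[, c("sample_id", "label", "confidence")], 3)
#>          sample_id label confidence
#> 1 newplatform_S001  NHMM          1
#> 2 newplatform_S002  NHMM          1
#> 3 newplatform_S003  NHMM          1

evaluate(calls, test$labels)
#> Accuracy 0.950 (95/100) at confidence > 0; 100 of 100 samples classified
#>       predicted
#> truth  HMM NHMM
#>   HMM   45    5
#>   NHMM   0   50
```

The second cohort has a different batch and 15% of genes missing, yet 95
of 100 planted labels are recovered; the five misses are "boundary"
samples simulated with both trisomies and the chr13 deletion, which by
construction sit between the two clouds. The paired copy-number profiles
give an independent truth call:

```r
cn <- call_hmm(test$copy_number, statistic = "median_ratio")
head(cn, 3)
#>          sample_id statistic_kind statistic cutoff label
#> 1 newplatform_S001   median_ratio  1.003557  1.125  NHMM
#> 2 newplatform_S002   median_ratio  1.011141  1.125  NHMM
#> 3 newplatform_S003   median_ratio  1.005454  1.125  NHMM
```

A ratio near 1 is a diploid trisomy-chromosome complement (2/2); HMM
samples sit near 1.5 (3/2). Here the copy-number calls agree with the
expression calls for 95 of 100 samples.

The same pipeline is scriptable from a shell via the thin CLI wrapper
(`inst/cli/hdmm`): `simulate`, `train`, `classify`, `cn-call`, `sweep-k`
and `evaluate` subcommands, each writing a provenance JSON beside its
outputs.

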