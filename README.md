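# nenstrat

Molecular stratification of lung neuroendocrine neoplasms (LNEN) from bulk
multi-omics data. Pulmonary carcinoids (typical and atypical) and large-cell
neuroendocrine carcinomas sit on a morphological continuum whose boundaries
correlate imperfectly with outcome; `nenstrat` implements an integrative
pipeline that derives molecular groups from expression and DNA methylation
jointly, confronts them with the histopathological labels, and characterises
the groups clinically and molecularly.

The pipeline's stages, each usable on its own:

* **Joint latent factors** — `fit_joint_factors()` stacks the feature-centred,
  variance-balanced expression and methylation blocks and decomposes them by a
  deterministic EM-style truncated SVD that tolerates samples missing one
  whole omic block. Samples get scores `Z`, features loadings `W`, and each
  factor a per-block fraction of variance explained; factors explaining more
  than 2% of variance in at least one block are retained
  (`select_factors()`).
* **Consensus clustering** — `consensus_cluster()` refits the factor model on
  100 random 80% subsamples, runs k-means (the first K−1 factors, or all
  factors weighted by variance explained) per subsample, aggregates
  co-clustering proportions into a consensus matrix, cuts its median-linkage
  hierarchy, and selects K by the Dunn index.
* **Dual-omic classification** — `classify_dual_omics()` runs leave-one-out
  random forests per omic with per-fold normalisation, feature selection and
  minority oversampling; a sample whose two highest class probabilities have
  ratio below 1.5 is "Unclassified", and discordant expression/methylation
  predictions merge to Unclassified.
* **Differential analysis** — `fit_moderated_pairwise()` fits moderated linear
  models with a fold-change-threshold null (threshold 2 on log2 expression by
  default), `core_features()` intersects pairwise hits per focal group, and
  `expr_meth_correlation()` screens promoter CpGs (±2000 bp of the TSS)
  against expression with q < 0.05, r² > 0.5, IQR > 0.25 filters.
* **Immune deconvolution** — `deconvolve()` estimates ten immune cell-type
  fractions per sample by non-negative least squares with a unit sum bound
  (the remainder is the non-immune "other" fraction);
  `group_fraction_tests()` compares fractions between groups with exact or
  Monte-Carlo permutation tests.
* **Survival** — `km_estimate()`, `cox_fit()` (Efron ties, Wald and logrank
  tests), `coxnet_select()` (elastic-net Cox, α = 0.5, leave-one-out CV,
  one-standard-error rule) and `maxstat_cutpoint()` (maximally selected rank
  statistics, ≥10% of samples per side).
* **Mutation enrichment** — `hallmark_enrichment()` tests hallmark gene sets
  for somatic-mutation enrichment by Fisher's exact test counting recurrent
  genes with multiplicity; `jackknife_leverage()` reports which single sample
  or gene flips each call.
* **Synthetic cohorts** — `generate_cohort()` draws seeded cohorts with three
  planted molecular clusters, a "supra" group whose morphology label
  contradicts its molecular profile, optional intermediate mixtures,
  cluster-dependent survival hazards, cluster-enriched mutations,
  methylation-driven genes and samples missing one omic block, so the whole
  pipeline is testable without controlled-access data.

`run_pipeline()` chains everything from a single configuration and seed and
writes TSV artifacts, a manifest and a plain-text report.

## Worked example

```r
library(nenstrat)

co <- generate_cohort(sim_config(seed = 42))
co
#> Synthetic multi-omics cohort
#>   samples: 120 (expression: 111, methylation: 111)
#>   genes: 1080, CpGs: 800, mutation genes: 23
#>   planted clusters: A=46, B=40, C=34

counts <- drop_sex_chromosome_features(filter_low_expression(co$expression),
                                       co$annotation)
en <- normalize_expression(counts)
mv <- beta_to_m(clamp_beta(co$methylation))
blocks <- list(expression  = en[select_variable_features(en, 0.5), ],
               methylation = mv[select_variable_features(mv, 0.05), ])

fm <- select_factors(fit_joint_factors(blocks, K = 5))
fm
#> Joint factor model: 2 factors, 120 samples, blocks: expression, methylation
#> Variance explained (%):
#>              LF1  LF2
#> expression  46.6 43.7
#> methylation 64.3 31.0

cc <- consensus_cluster(blocks, R = 100, seed = 1)
cc
#> Consensus clustering: R = 100 replicates, subsample = 80%, mode = kminus1
#> Dunn index per K:
#>      2      3      4      5
#>  4.106 50.073  0.174  0.103
#> Chosen K: 3
#> Cluster sizes at chosen K: 46, 40, 34
```

The first two factors carry the cluster structure (91% of expression
variance, 95% of methylation variance between them), the Dunn index peaks
sharply at K = 3, and the consensus labels match the planted clusters exactly
(adjusted Rand index 1.0 for this seed). Survival then separates the groups
as planted — cluster B and the high-grade cluster C have exponential hazards
3.3× and 9× that of cluster A, and the fitted Cox model recovers that
ordering:

```r
cl <- co$clinical
truth <- setNames(co$truth$cluster, co$truth$sample_id)
cox_fit(cl$os_months, cl$os_event, truth[cl$sample_id], reference = "A")
#> Cox proportional-hazards fit (reference: A )
#>  level    hr lower upper   wald_p  n
#>      B  5.96  3.17  11.2 3.14e-08 40
#>      C 20.70  9.36  45.8 7.25e-14 34
#> Global logrank (score) p: 6.41e-17
```

(Point estimates at n = 120 are noisy; the coverage simulation in the
acceptance script shows the Wald intervals are calibrated.)

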