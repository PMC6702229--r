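---
title: "Methods: multi-omics stratification of lung neuroendocrine neoplasms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics stratification of lung neuroendocrine neoplasms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `nenstrat`: the models
and their assumptions, the tunable parameters, the synthetic-cohort generator
the tests run on, and the numerical and design choices made where the
methodology left room.

## The joint factor model

Expression counts are transformed to `log2(count / size_factor + 1)` with
median-of-ratios size factors; methylation beta values are mapped to M-values
`log2(beta / (1 - beta))`. Each block is centred per feature and rescaled to
unit total variance so neither block dominates, stacked, and decomposed by a
rank-K truncated SVD. Samples absent from one block enter as missing columns
of that block: an EM-style iteration imputes them from the current rank-K
reconstruction (zeros initially), re-decomposes, and repeats. Scores are
`Z = V D`, loadings `W = U`; factors are ordered by total variance explained
and signed so each factor's largest-magnitude loading is positive. The
per-block variance explained by factor k is
`||w_k z_k'||^2 / ||X_block||^2` over that block's observed entries.

This is a deliberate deterministic surrogate for variational-Bayes group
factor analysis: it assumes linear factors, homoscedastic residuals within a
block, and equal a-priori weight for the two blocks. It has no sparsity
prior and no automatic factor-number inference; instead, fitted factors are
retained when they explain at least 2% of the variance in at least one block
(`select_factors()`), and `factor_stability()` refits under seeded
perturbations of the initial imputation in place of multi-run model
selection (20 runs by default).

**Stopping rule.** The iteration stops when the relative change of the rank-K
reconstruction falls below `tol` (1e-6) *or* when the relative per-iteration
decrease of the observed-data residual sum of squares falls below `obj_tol`
(1e-4). The second rule matters when K exceeds the true rank: near-degenerate
noise singular values rotate indefinitely, so the reconstruction keeps
changing while the objective — which is non-increasing under the EM update,
a property the test suite asserts on the recorded trace — is flat. A fit that
reaches `max_iter` (300) without meeting either rule is returned with a
warning and `converged = FALSE`.

**Recovery quality.** On noiseless low-rank data the fit equals the truncated
SVD exactly (machine precision; single pass when nothing is missing). On the
default synthetic cohort the test suite asserts that the subspace spanned by
the two cluster-bearing factors is recovered to within 15 degrees of
principal angle. The binding constant is the number of informative features
(roughly a hundred genes and a few dozen CpGs after variance-fraction
selection), which sets a per-sample score-estimation floor of several
degrees; factors without between-cluster signal are essentially
unidentifiable at this problem size, which is why factor retention and
clustering rely only on the leading factors.

## Consensus clustering

Each of `R = 100` replicates draws 80% of the samples without replacement,
refits the factor model, and clusters the replicate scores with Lloyd k-means
(own k-means++ seeding, 10 restarts per replicate and 25 in direct calls,
best within-cluster sum of squares kept). Two modes: `kminus1` clusters on
the first K−1 factors; `weighted` uses all fitted factors with per-factor
weight equal to its variance-explained share, implemented by scaling each
coordinate by the square root of its weight. The consensus value of a sample
pair at K is the fraction of replicates sampling both in which they
co-cluster; pairs never co-sampled are an error (increase R) rather than an
imputation. Final labels cut the median-linkage hierarchy of `1 - C` at K.

**Choice of the Dunn space.** K is chosen by the Dunn index (minimum
between-cluster distance over maximum cluster diameter). Where that index is
evaluated was an open choice; `nenstrat` evaluates it on the consensus
dissimilarity `1 - C` by default. The factor-coordinate variant
(`dunn_on = "factors"`) is retained, but because Dunn is a min/max statistic
it rewards peeling single noisy samples into their own clusters at large K,
which makes K selection unstable on realistic noise; consensus dissimilarity
asks instead which K yields clusters that co-occur in nearly all replicates,
and selects the planted K decisively in the package's tests. All fitted
factors (not only the retained ones) stay available to the replicates so the
K−1 rule is feasible up to `n_factors + 1` clusters.

## Dual-omic classification

Per omic, a leave-one-out cross-validation: in each fold, low-expression
filtering (counts-per-million ≥ 1 in ≥ 2 samples), normalisation, selection
of the most variable features explaining 50% (expression) or 5%
(methylation) of training variance, and centring/scaling are all learned on
the training samples and applied to the held-out sample — the learned
size-factor reference profile is how the count transform transfers to new
samples. Minority classes are then oversampled with replacement to the
majority size (after feature selection, so duplicated samples do not inflate
the variances used for selection), and a 500-tree random forest with
sqrt(p) candidate features per split is trained; class probabilities are
tree-vote fractions. Technical replicates share a fold and are never split
across training and test.

A sample is **Unclassified** when the ratio of its two highest probabilities
is strictly below `rho = 1.5`; a ratio exactly 1.5 classifies, and an exact
tie of the top two probabilities is always Unclassified since the argmax is
undefined (at `rho = 1` this is the only route to a single-omic
Unclassified). Merging: one omic only → that prediction; equal → that label;
class + Unclassified → the class; two different classes → Unclassified.
Survival comparisons use (histology, prediction) groups with more than 10
samples, all Unclassified samples pooled.

## Differential analysis

One engine serves expression and methylation: per feature, a linear model
`value ~ group + covariables`; residual variances are shrunk towards an
empirical-Bayes prior estimated by moment matching on the log variances
(digamma/trigamma identities, own trigamma inverse), and the statistic tests
the null that the absolute group difference is at most `theta`:
`t = sign(b) max(|b| - theta, 0) / (s_tilde c)` on `d0 + d` degrees of
freedom. `theta = 2` on the log2 scale for expression (the fold-change
threshold), 0 for methylation; `d0 = 0` recovers the classical t and
`d0 = Inf` pools all features, both exposed for diagnostics. The test suite
cross-checks the default moderation against an independent
empirical-Bayes implementation (limma) to 1e-8. This unifies what the
original analyses did in two frameworks (negative-binomial Wald tests for
counts, array linear models for methylation); it is a surrogate — no count
likelihood, no shrunken fold changes — chosen so one tested engine serves
both omics on their normalised scales.

Core features of a focal group are the intersection of its pairwise
significant sets (BH q < 0.05 within each pair) with a consistent effect
direction relative to the focal group; direction consistency is this
package's reading of "core" (focal-specifically up *or* down) and can be
disabled. Promoter correlation maps CpGs to genes within ±2000 bp of the TSS
(boundary inclusive, multiple genes allowed), tests Pearson correlation per
pair, adjusts across all pairs, and keeps pairs with q < 0.05, r² > 0.5 and
beta-IQR > 0.25, reporting the smallest-q CpG per gene.

## Deconvolution, survival, enrichment

**Deconvolution** solves `min ||S f - b||` with `f ≥ 0` and `sum(f) ≤ 1` per
sample: non-negative least squares first; if the sum bound is violated, the
support found by a penalty-augmented NNLS is refined by the exact
KKT solution of the equality-constrained problem. The remainder `1 - sum(f)`
is the non-immune fraction. Group differences use permutation tests on the
mean difference (the two-level linear-model coefficient): exhaustive
enumeration whenever the number of splits fits the permutation budget,
otherwise seeded Monte Carlo with the add-one correction; BH across cell
types within each pair.

**Survival.** Kaplan–Meier and Cox fits go through the survival package
(Efron ties by default, Breslow by flag); Wald tests per level against the
reference and the global score (logrank) test are reported, and monotone
likelihoods are flagged rather than silently returned. Elastic-net Cox uses
alpha 0.5 on a 100-value lambda path spanning four decades with leave-one-out
cross-validated partial-likelihood deviance and the one-standard-error rule;
an empty selection is a valid, flagged result. Maximally selected rank
statistics enumerate every cutpoint leaving at least 10% of samples per
side and return the split maximising the standardized logrank statistic; the
reported p-value is the unadjusted logrank p of the chosen split (the
selection-adjusted p is out of scope). Survival time is months throughout.

**Mutation enrichment** builds, per gene set, a 2×2 table of mutation events
in-set versus out-of-set against universe gene membership, counting recurrent
genes with multiplicity (a presence/absence mode is provided, since the
original contingency construction is ambiguous), tests two-sided by Fisher's
exact test, adjusts within group, and flags q < 0.05 and q < 0.10. The
universe defaults to all mutated genes plus all set genes. Jackknife
leverage re-runs the analysis leaving out each sample or gene and reports
significance flips at both thresholds.

## The synthetic cohort

`sim_config()` defaults describe a 120-sample cohort: three molecular
clusters (46/40/30) whose latent-factor means are separated by 4–5 within-
cluster standard deviations, plus four "supra" samples carrying cluster-B
morphology with the high-grade cluster-C molecular profile. Intermediate
samples (convex mixtures of the A and B profiles with mixing weight uniform
on 0.35–0.5, morphology alternating between the two mixed labels, as
morphologically ambiguous cases draw inconsistent calls) are off by default —
the default cohort is the three-cluster design — and are switched on by the
classifier tests. Expression counts are negative binomial (dispersion 0.1,
i.e. size 10) with log-mean = gene offset + loadings × scores + log library
size; methylation M-values are loadings × scores + Gaussian noise (sd 1,
chosen so CpG variance is not concentrated in a handful of probes), mapped
to beta and clamped to [1e-6, 1 - 1e-6]; 50 genes are methylation-driven
(expression suppressed by a promoter CpG's M-value, the CpG placed within
±1800 bp of the gene's TSS). Survival is exponential with per-cluster log
hazards (−4.8, −3.6, −2.6 per month); a sample is censored with probability
`censor_rate`, its observed time then uniform on (0, T). Mutations are
Bernoulli with cluster-enriched rates over a small recurrent panel; immune
marker genes mix a bundled synthetic signature at cluster-specific fractions
(supra samples dendritic-cell rich); ten X- and ten Y-linked genes make the
sex-concordance check testable; 8% of samples lack each omic block
(disjoint sets, absent columns).

The generator emulates the statistical structure the analyses assume — not
real data. It has no batch effects beyond a label, no CpG co-methylation or
gene–gene correlation beyond the shared factors, no probe artefacts,
realistic coordinates or linkage, and cluster separations chosen for
testability (the effect sizes separating real molecular groups are not
known). Passing tests therefore demonstrate that the machinery recovers
planted structure of this kind at these sizes; they say nothing about
classification accuracy, cluster counts or survival contrasts in real
cohorts.

## Numerical choices and test problem sizes

Feature-selection ties break by feature id; beta values are clamped before
the M-transform; k-means uses seeded k-means++ with multiple restarts so the
best-inertia solution is reproducible; stage seeds derive from one global
seed by hashing the stage name, so every pipeline stage is independently
reproducible and two runs with the same configuration write byte-identical
artifacts. Cohort files serialise numerics at full precision (`%.17g`) so a
write/read round trip is exact.

The test suite and acceptance script run at desk scale, chosen to finish in
minutes on one CPU: the consensus-recovery check uses the default
120-sample cohort with R = 100; classifier checks use a 96-sample cohort
with 16 intermediates, and the permutation-null check uses 8 permuted
leave-one-out runs with 300-tree forests; Cox coverage uses 200 simulations
of n = 200; deconvolution and moderated-test nulls use 200 replicates and
20 × 2000 features respectively. These sizes are the package's choices for
its own validation; all of them are parameters.

## Known limitations

The factorisation is a surrogate (no posterior uncertainty, equal block
weighting); the expression transform is a log-based stand-in for a
count-model variance-stabilising transform, with the learn/apply contract
preserved via the reference profile; differential tests are moderated linear
models rather than count likelihoods; factor recovery at realistic noise is
limited by the informative-feature count (see above); the maxstat p-value is
not selection-adjusted; deconvolution assumes the signature and bulk share a
linear normalised scale and ignores mRNA-content differences between cell
types.
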