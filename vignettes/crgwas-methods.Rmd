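---
title: "Methods: composite resequencing-based association mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite resequencing-based association mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Resequencing a panel of inbred accessions at candidate gene fragments
yields a variant spectrum dominated by rare alleles: in such panels about
half of all SNPs have minor allele frequency (MAF) below 5%, and the
rarer a nonsynonymous variant is, the more likely sequence-homology tools
(PolyPhen, SIFT) are to predict it protein-damaging — a signature of weak
purifying selection. Single-marker association tests are nearly powerless
for such variants, because a SNP carried by one or two accessions cannot
by itself produce a significant regression. `crgwas` implements a
composite strategy: common variants are tested marker-by-marker and
jointly per fragment, rare variants are collapsed into per-individual
burden scores, significance is calibrated by permutation, and the
resulting hits are filtered through prior biological knowledge — a
curated candidate-gene list and a probabilistic functional gene network.

## Phenotype preparation

Missing phenotype entries (a few percent in typical multi-trait panels)
are imputed from correlated traits: each trait is standardized, a missing
cell is filled with the correlation-weighted mean of the sample's `k`
most-correlated observed traits (default `k = 3`, absolute pairwise
correlation over complete pairs, the correlation's sign carried through),
and the result is mapped back to the target trait's scale. The procedure
is deterministic; the published account of the analogous step names only
"a clustering method", so this explicit k-nearest-trait scheme is this
package's own concrete choice and is documented as such. Completed traits
are then rank-transformed to normal scores (Blom offset 3/8, midranks for
ties, columns centered), which makes the Gaussian likelihood-ratio
machinery downstream insensitive to trait scale and outliers.

## Structure adjustment: mixed model and GRAMMAR

Phenotypes in structured panels are modeled as

    y = X beta + u + e,   Var(u) = 2 K sigma_g^2,   Var(e) = I sigma_e^2,

so the phenotypic covariance is `V = 2K sigma_g^2 + I sigma_e^2`. `K` is
a marker-based kinship matrix; the estimator used here is allele-sharing
similarity rescaled so the average pair of the panel has kinship zero,
with the diagonal set to 1 and a nearest-PSD projection (eigenvalue
clipping followed by correlation rescaling) applied when the truncation
at zero leaves small negative eigenvalues. The published source does not
print its kinship formula, so the estimator is pluggable: any symmetric
PSD matrix can be supplied in its place.

With a single random effect the REML criterion profiles down to one
dimension. Writing `2K = U D U'` and rotating `y` and `X` by `U'`, the
model becomes a weighted regression with weights `1/(1 + delta d_i)`
where `delta = sigma_g^2/sigma_e^2`; `delta` is found by Brent search on
the log scale (tolerance 1e-8, with `delta = 0` always evaluated as a
boundary candidate), and fixed effects follow by generalized least
squares. The implementation is verified in the test suite against a
generic two-dimensional optimizer of the full REML expression.

Candidate structure models — a null intercept model, genotype principal
components, or file-supplied STRUCTURE/nMDS coordinates, each with and
without the kinship term — are compared per trait by BIC. BIC uses the
*maximum-likelihood* log-likelihood (maximized over the same profile),
not the REML one, so models with different fixed-effect counts are
comparable; the parameter count is fixed effects plus estimated variance
components. The published work compared 22 such models; their exact
composition is not recoverable from the text, so the grid here is
configuration, not fixed behavior.

Testing then follows the two-stage GRAMMAR strategy: the selected model
is fitted once per trait, and all marker tests use the adjusted phenotype
`y_adj = y - X beta_hat - u_hat`, where `u_hat` is the polygenic BLUP.
This trades a small loss of power for an enormous computational saving
and removes the convergence fragility of refitting a mixed model per
marker. Because GRAMMAR residuals can remain slightly over- or
under-dispersed, single-SNP statistics are additionally passed through
genomic control: `lambda = median(LR)/0.4549`, dividing by
`max(lambda, 1)`. The deflation-only default reflects that dividing by a
`lambda < 1` would anti-conservatively inflate statistics; symmetric
adjustment is available as a flag.

## The test battery

All tests are Gaussian likelihood-ratio tests on the adjusted phenotype,
`LR = n ln(RSS0/RSS1)`, referred to a chi-square with as many degrees of
freedom as fitted regressors. Per fragment:

* **Single SNP** (`lr_test`): one regression per polymorphic SNP,
  Bonferroni-controlled (`alpha/M`), because permutation over a full SNP
  panel is computationally disproportionate.
* **Multivariate common-variant test**: all common SNP columns of a
  fragment jointly, collinear columns reduced by QR pivoting in input
  order.
* **Rare-variant collapsing tests**, applied only when a fragment
  carries `m >= 3` rare variants (MAF < 5%, strict; the cutoff of three
  avoids treating two rare alleles in complete linkage disequilibrium as
  independent evidence):
  * *sum*: `z_i = (sum_j x_ij)/m`;
  * *weighted sum*: `z_i = sum_j x_ij / sqrt(n p_j (1 - p_j))`, the
    classic inverse-binomial-SD weighting that up-weights the rarest
    alleles;
  * *function-aided sum*: `z_i = sum_j S_j p_j^F x_ij`, where `S_j` is a
    per-category damage weight (mean PolyPhen delta scores: 0.6772 for
    benign or synonymous, 1.7051 for possibly damaging, 2.4277 for
    probably damaging; nonsense changes take the top weight) and `p_j^F`
    is the predicted proportion of functional SNPs at the variant's MAF
    from the fitted power law described below.
* **Combined multivariate pooled test**: for fragments with both common
  variants and a valid pooled rare score, the common columns plus the
  weighted-sum score enter one joint regression.

Sample MAFs enter the weights with no pseudo-count, so a single-carrier
variant contributes `p = 1/n` under ploidy 1. `p_j^F` is used unclipped
as a weight (its clipped companion is reported for display), since only
the relative weighting matters in the score.

## The MAF-to-function power law

Nonsynonymous SNPs are binned by MAF into twenty 2.5%-wide, left-open
right-closed bins over (0, 0.5]; the per-bin proportion predicted
functional is regressed on the bin midpoint under three models: power
(`a p^b`, ordinary least squares on the log-log scale, zero-proportion
bins excluded rather than offset by an arbitrary constant), logarithmic,
and linear. R-squared is always computed on the original proportion
scale so the three models are comparable; whether the published values
used the transformed or original scale is not stated, and the choice is
switchable. MAF units in the regression default to *percent*: the
published coefficients only yield proportions at most 1 over the
observed range when `p` is a percentage. The bin representative defaults
to the midpoint (per-bin mean MAF is selectable). On noise-free data
generated from the published PolyPhen curve the estimator returns
`a = 0.3562`, `b = -1.4162` to machine precision, which is what the
acceptance script recomputes.

## Permutation calibration and LR/LR99

Experiment-wise thresholds come from permutation: for each (trait,
method) battery the adjusted phenotype is permuted (default 1000 times,
seeded), the maximum LR across all testable fragments is recorded, and
`LR99` is the empirical 99th percentile (type-7 interpolation) of the
maxima. The scope — maximum across fragments within a trait and method —
is this package's reading of "experiment-wise"; it is configurable.
Permuting the *adjusted* phenotype is consistent with the GRAMMAR
two-stage logic (structure is removed once; exchangeability then holds
approximately under the null). Dividing each LR by its battery's LR99
puts the methods on one scale: `LR/LR99 >= 1` is experiment-wise
significant at the 1% level, and ratios are comparable across methods
because scaling all of a method's statistics and its threshold by a
constant leaves the ratio invariant.

The chi-square reference for the LR is asymptotic, and its quality
degrades with the degrees of freedom: at `n` around 100 a df-5
multivariate LR rejects a true null at roughly 6% instead of 5%. This is
precisely why the pipeline's operative significance calls rest on
permutation rather than asymptotics. The test suite therefore checks
asymptotic type-I error where the approximation is in its operating
range (n = 200 for single-regressor tests, n = 500 for the joint tests)
and checks the permutation threshold's experiment-wise control at panel
scale (n = 96).

## Decision layer

Scaled results pass through four filters mirroring the composite
strategy: (1) a tested unit whose gene is on the a priori candidate list
is *confirmed* when it is significant at the 0.001 level under **every**
method applicable to it (permutation p-values when available, else
asymptotic; the source is recorded); (2) units not on the list are
triaged to the top 30 tests by LR/LR99 (ties broken by LR then unit id,
a deterministic rule the source text does not specify); (3) a fragment
needs at least three predicted-functional SNPs to count as functionally
supported; (4) cross-method consistency (Venn intersection of the three
collapsing tests' significant sets) narrows the list further.

## Gene network interrogation

The gene network is an undirected graph with positive log-likelihood
scores (LLS) on edges. Query candidate genes are partitioned into
connected (at least one edge to another query), disconnected, and absent.
A gene's retrieval score against a seed set is the *sum* of LLS over its
edges into the seed set — the additive choice matches the
Bayesian-integration semantics of such networks (max-edge scoring is a
configuration alternative). Seed-set quality is the Mann-Whitney AUC
(midranks for ties) of leave-one-out seed scores against all non-seed
network genes scored on the full seed set; scoring negatives against the
full set rather than per-fold keeps the evaluation deterministic. Seeds
are pruned iteratively — remove the lowest-scoring seed (ties:
lexicographically smallest id) until AUC >= 0.95 — and the retained
seeds retrieve their top-200 non-seed neighbors, whose intersection with
the top association hits yields posterior candidates.

One finite-size caveat, visible in the null tests: a seed is scored
against one fewer potential partner than a non-seed, so with very small
seed sets the null AUC sits slightly below 0.5. The effect is O(1/s) in
the seed-set size and negligible for seed sets of 20 or more.

## The synthetic panel generator

The generators produce data with the statistical structure the pipeline
assumes, so every stage is testable without any external download:

* **Genotypes**: per-SNP target MAFs from a rare/common mixture (rare
  with probability 0.5; rare MAFs uniform on (1/n, 0.05), common uniform
  on [0.05, 0.5]), realized by placing the corresponding number of
  carrier accessions, with carrier choice biased across subpopulations
  by a divergence parameter. Carrier-count placement (rather than
  per-sample Bernoulli draws) keeps the realized spectrum on the
  targeted side of the 5% boundary, matching the roughly 50% rare
  fraction such panels show; the realized MAF is still recomputed from
  the sampled calls. Within-fragment linkage is not modeled: the
  pipeline consumes genotype columns, not haplotypes.
* **Annotations**: each nonsynonymous SNP is functional with probability
  `min(1, a p^b)` (percent MAF, PolyPhen-curve defaults), split between
  probably- and possibly-damaging; SIFT calls agree with the truth 85%
  of the time so the two predictors are congruent but not identical, as
  observed in real panels.
* **Phenotypes**: subpopulation mean shifts plus a polygenic term with
  covariance `2K sigma_g^2` (heritability default 0.3) plus causal
  rare-allele effects plus unit Gaussian noise. The default causal
  effect is 1.5 residual SD per allele — rare variants of large effect,
  the allelic architecture the collapsing tests are designed for — and
  under the `s_weighted` model each causal SNP's effect is proportional
  to `S_j p_j^F`, the generative regime in which the function-aided test
  should dominate the unweighted sum test. Truth records (causal
  fragments, SNPs, effects) are first-class outputs.
* **Networks**: a planted seed clique with high LLS over background
  noise edges that are blind to cluster membership.

What the generator does *not* emulate: linkage disequilibrium within and
between fragments, genotyping error, selection-driven site-frequency
spectra, trait-trait genetic correlation, and real network topology.
Passing tests therefore demonstrate correctness of the statistical
machinery under its own assumptions, not performance on any real panel.

## Problem sizes and numerical choices

The shipped test suite uses panels of 40-300 accessions, 10-600
fragments, permutation counts of 120-300, 10^4-replicate null
calibrations, and 15-25 replicate end-to-end runs; these sizes were
chosen so the whole suite completes in a couple of minutes while leaving
the binomial confidence intervals tight enough to detect real
miscalibration. Degenerate inputs are handled explicitly: constant
regressors and constant traits are errors; monomorphic SNPs are excluded
and counted; a perfect fit caps the LR with a warning; fragments with
fewer than three rare variants are excluded with a recorded reason;
permutation batteries skip failing fragments consistently across
permutations; and ties are broken deterministically everywhere
(documented per function). All randomness is seeded and every generator
is a pure function of its specification.

## Known limitations

* The GRAMMAR approximation deflates per-marker effect sizes; `beta1`
  estimates are conservative and no exact per-SNP mixed-model score test
  is provided.
* Only one random effect (kinship) is supported — no multi-kernel or
  interaction models.
* The congruency test and the damage-category weights treat predictor
  categories as fixed inputs; the package never runs PolyPhen or SIFT.
* Phenotype imputation assumes trait-trait correlation is informative;
  with uncorrelated traits it degrades to column means.
* The network stage consumes an edge list as-is; it neither constructs
  nor rescales LLS values.
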