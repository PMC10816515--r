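---
title: "Bridging shotgun and 16S microbiome data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridging shotgun and 16S microbiome data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxbridge)
```

## The problem

A microbial signature is the set of taxa carrying non-zero coefficients in a
penalized prediction model — here, a logistic model that scores a stool
sample's colorectal-cancer risk from species-level shotgun abundances plus
sex, age and BMI. 16S rRNA amplicon sequencing is far cheaper than shotgun
sequencing but reports a different, coarser view of the same community:
many taxa are nameable only at genus level or above, counts are much
sparser, per-taxon amplification bias distorts relative abundances, and the
reference taxonomy differs. Before a shotgun-trained model can score 16S
data, every signature taxon needs exactly one 16S counterpart.

`taxbridge` builds that correspondence in two steps and then quantifies what
the transfer costs.

## The harmonization algorithm

**Taxonomic step.** Both taxonomy tables are first standardized to a common
nomenclature with `standardize_taxonomy()` — a purely offline application of
a rank-qualified name map (a snapshot of a reference resolver); no live
queries, so results are reproducible. Shotgun catalogues decorate names with
single-letter clade suffixes ("… fragilis A") and placeholder identifiers
for unnamed species; `normalize_lineage_names()` strips the suffixes and
treats placeholders as unnamed at species rank, so matching proceeds from
the genus or family in the lineage. `rank_ladder_search()` then looks for
the query's name in the target table at species rank, ascending
genus → family → order → class → phylum until candidates appear. The ladder
runs past order up to a configurable cap (`max_rank`, default `"phylum"`):
in typical data everything resolves by order, but nothing in the algorithm
requires stopping there. Name comparison is case-insensitive and
whitespace-normalized *exact* matching — fuzzy matching is deliberately
excluded because its decisions are unreviewable. When one genus name occurs
under two distinct families in the target, both lineages enter the candidate
pool and the distance step decides.

**Data-driven step.** A singleton pool is accepted as a purely taxonomic
assignment. Any pool larger than one — including multiple same-named
species-level entries — goes to profile matching: over the paired samples
(same specimens sequenced with both technologies), the candidate whose clr
abundance profile has the smallest Euclidean distance to the target's
profile wins. Samples act as variables; taxa are the points being compared.
Exact distance ties (measure-zero on real data) break to the
lexicographically smallest taxon ID so the mapping is deterministic. A
Spearman-based dissimilarity (`1 − ρ`) is available via `metric =
"spearman"` for users who prefer rank agreement over magnitude agreement;
the default follows the Euclidean convention.

Two shotgun taxa may legitimately share a 16S partner (e.g. two congeneric
species collapsing onto one genus-level taxon); this is permitted with a
warning. `strict = TRUE` instead assigns greedily in signature order,
skipping already-used candidates — appropriate when the downstream model
cannot tolerate duplicated feature columns. Each mapped pair also records
whether its partner attains the minimum distance over *all* 16S taxa
(`distance_rank_check()`): a high count of such "absolute minima" indicates
the data-driven signal alone, without taxonomic guidance, points to the same
biology.

## Compositional preprocessing

Counts are compositions, so all comparisons happen in log-ratio coordinates.
The pipeline, in order:

1. **Genome-length normalization** (shotgun only): read counts divided by
   genome length in bp, converting reads to genome copies. 16S counts have
   no analogous correction, so it is skipped there.
2. **Prevalence filter**: keep a taxon if its within-sample relative
   abundance reaches `min_rel_abundance` (default 0.001) in at least
   `ceiling(min_prevalence × n)` samples (default 5%). Applied after length
   normalization, on the matrix entering the filter. The same criteria are
   imposed on both technologies to keep the matrices comparable, accepting
   that the sparser 16S matrix loses proportionally more taxa.
3. **Zero replacement**: the square-root Bayesian-multiplicative scheme. For
   sample *i* with depth `n_i` over `D` taxa, the Dirichlet prior has
   uniform mass `t_j = 1/D` and total strength `s_i = √n_i`; each zero
   becomes `s_i t_j / (n_i + s_i)` of the composition and the non-zero parts
   are rescaled multiplicatively, which preserves their ratios exactly —
   the property log-ratio analysis depends on.
4. **clr transform**: `ln(x_j / g(x))` with `g` the row geometric mean.
   Rows sum to zero (tested at 1e−9) and the transform is invariant to row
   rescaling.

Alpha diversity is described on the *filtered counts before zero
replacement*: bias-corrected Chao1
(`S_obs + F1(F1−1) / (2(F2+1))` — defined even with no doubletons, which is
why the bias-corrected variant was chosen) and Shannon entropy in nats
(base-2 via the `base` argument), the latter computed on counts rarefied to
the minimum sample depth. Rarefaction is a single seeded
without-replacement subsample, not an average over repetitions — one draw,
recorded seed, reproducible.

## Performance evaluation

- **AUC**: the Mann–Whitney statistic (ties count half), with a percentile
  CI from 2000 class-stratified bootstrap resamples under a recorded seed.
  Stratification matters because the intended use case is heavily
  imbalanced test sets. No asymptotic (DeLong-style) intervals are offered.
- **Covariate-adjusted AUC**: when the compared groups differ in sex, age or
  BMI, raw AUC conflates microbial signal with covariate signal. Following
  the placement-value construction, a linear location model of the score on
  the covariates is fitted among controls; each case's placement value is
  the fraction of control residuals below its own residual (ties half); the
  adjusted AUC is the mean placement value. The placement-value framework
  admits several estimators; the linear-residual version was chosen as the
  most transparent, and the bootstrap *refits the covariate model in every
  resample* so the interval reflects estimation uncertainty in the
  adjustment itself. Constant covariates are dropped with a warning.
- **Threshold metrics**: specificity, sensitivity and precision at a
  probability cutoff (default 0.33). The boundary `p == threshold`
  classifies as case — an arbitrary but documented and deterministic choice.
  Precision is reported as `NA` when nothing is predicted positive.
- **Ordination**: PCA of the column-centred clr matrix via SVD with no
  per-taxon scaling (clr coordinates already share a scale). New samples
  project through the training centre and loadings. Procrustes comparison
  uses symmetric scaling (both configurations normalized to unit sum of
  squares) with the correlation `r = √(1 − m12²)` and a 999-permutation
  test, delegated to vegan's protest.

## The paired-data generator

`simulate_paired()` exists so every claim above is testable against known
ground truth. Its generative model:

- a latent species community per sample: log abundances
  `μ_j + g_{i,genus(j)} + ε_ij`, with between-species spread
  `σ_species = 1.5`, a genus-block random effect `σ_genus = 0.5` shared by
  genus mates (making congeneric profiles correlated, the hard case for the
  distance step), and a species-level per-sample effect `σ_sample = 1.0`
  (the signal the distance step keys on), closed by softmax;
- shotgun observation: multinomial at depth 1e5 — the matrix comes out
  dense (a few percent zeros), as species-level pipelines do;
- 16S observation: per-taxon log-normal amplification bias (sd 0.3),
  per-entry log-normal observation noise (sd 0.3), loss of species-level
  resolution for 60% of species — their reads collapse into a genus-level
  taxon, mirroring the reported fraction of 16S taxa nameable only above
  species — multinomial at depth 2e4, then dropout thinning: the smallest
  non-zero entries (random order within ties, never a sample's largest
  entry) are zeroed until the matrix-wide zero fraction hits the 0.61
  target. Dropout is needed because multinomial sampling alone cannot reach
  realistic 16S sparsity at these depths; as a consequence 16S row sums
  fall below the nominal depth (shotgun row sums equal theirs exactly);
- a 32-species signature drawn from the more abundant half of the community
  (rare species would not survive the prevalence filter on either side),
  effects `±Uniform(0.5, 1.5) × 0.5` on the latent clr scale; covariates
  sex ~ Bernoulli(0.5), age ~ N(60, 8), BMI ~ N(27, 4) on epidemiological
  scales, with small logistic coefficients; the intercept centres the
  linear predictor so cases and controls are roughly balanced, matching a
  validation-cohort design.

What the generator does **not** emulate: read-level artefacts (chimeras,
primer mismatch), taxonomy disagreements between reference databases (both
tables share nomenclature by construction, so `standardize_taxonomy()` is
exercised on hand-built fixtures instead), batch effects between cohorts,
and ecological interactions between taxa. Passing tests on synthetic data
therefore demonstrate algorithmic correctness and calibrated behaviour
under this model, not performance on any particular real cohort.

Default problem sizes used throughout the test suite — 150 paired samples ×
400 species for study-condition runs, 40–120 samples × 80–200 species for
the randomized oracle instances, 10 seeds per benchmark — keep each
property suite in the seconds-to-a-couple-of-minutes range while leaving
enough resolution to detect calibration drift.

## Numerical and degenerate-input conventions

- clr row sums asserted to 0 within 1e−9; zero-replacement ratio
  preservation within 1e−9 relative; distance-tie and absolute-min
  comparisons within 1e−9.
- All-zero samples are an error everywhere (they have no composition);
  all-zero candidate pools are an error in `map_signature()` (the taxonomy
  failed) but a valid `NA` result in `rank_ladder_search()` (absence is an
  answer).
- Constant profiles under the Spearman metric get the maximal dissimilarity
  (ρ undefined → distance 2) rather than propagating `NA`.
- Every stochastic routine (bootstrap, rarefaction, permutation test,
  simulation) takes an explicit seed and restores the caller's RNG state.

## Known limitations

- The mapping is computed taxon by taxon; joint assignment that accounts
  for interactions between taxa is out of scope.
- Abundance-profile matching needs paired samples; with few pairs the
  distance step can mistake noise for signal, and an independent 16S test
  set is the honest way to estimate post-transfer performance.
- The rank ladder requires both taxonomies to speak the same nomenclature;
  the quality of the offline name map bounds the quality of step 1.
- Sequence-based matching (OTU/ASV) is not attempted — only names and
  abundance profiles are used.
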