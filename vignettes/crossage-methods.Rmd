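---
title: "Methods: age-associated transcript selection and directed association networks"
author: "crossage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-associated transcript selection and directed association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bulk transcriptomes of multi-organ aging cohorts are dominated by nuisance
variation: in a factorial mouse design spanning several organs, two strains,
both sexes and five sampling ages, the organ explains the overwhelming share
of expression variance, while age — the factor of interest — contributes well
under one percent. Linear two-group screens on such data miss weak,
nonlinear and interaction-borne age signal. `crossage` implements a pipeline
built around three ideas:

1. **Harmonize first, and choose the correction order empirically.** Nuisance
   factors (organ, strain, sex) are removed one at a time, by within-group
   z-scoring or empirical-Bayes location/scale adjustment (ComBat), each step
   fitted within the strata of the factors already corrected. Because the
   steps are not exchangeable on real (FPKM-like, hence multiplicative-scale)
   data, every permutation of covariates and methods is evaluated and ranked
   by the age variance fraction under principal variance component analysis
   (PVCA); the plan with the strongest age fraction wins.
2. **All-relevant selection with shadow features.** A random forest is fit to
   the harmonized frame with every feature accompanied by a permuted "shadow"
   copy. A feature scores a *hit* when its importance exceeds the best shadow
   importance; accumulated hit counts are classified by a two-sided binomial
   test (Bonferroni-corrected over the undecided attributes) into
   confirmed / tentative / rejected. The whole selection is iterated with
   independent seeds and aggregated: a transcript is in the *hit set* when it
   is nonrejected (confirmed or tentative) in at least a configurable number
   of iterations, and its association strength is the iteration mean of its
   mean importance (`meanImp`) and hit rate (`normHits`). Age is analyzed
   both as a number (NVA) and as a class label (CVA); the union of both hit
   sets feeds the downstream stages.
3. **Directionality from per-target selection.** Running the selection once
   per transcript — each transcript in turn as the target variable, all
   others as predictors ("CrossBoruta") — yields a *directed* edge table:
   an edge target → feature says "the target's model selected this feature",
   with its own strength and stability. Asymmetries in this table are
   informative: the **asymmetric association strength** of transcript $i$ is
   $$\mathrm{AAS}(i) = \frac{\sum_{\text{in-edges of } i} \text{meanImp}}
                            {\sum_{\text{out-edges of } i} \text{meanImp}},$$
   the summed weight of $i$ as a *selected feature of others* over the summed
   weight of $i$'s own selections. $\log_2 \mathrm{AAS} > 0$ marks a
   transcript that many depend on while it depends on few — a putative
   hierarchically superior actor. A transcript that is never a target has no
   defined AAS and carries an explicit "no value" sentinel.

## The synthetic cohort generator

The generator is first-class, tested code: it produces the study conditions
under which every downstream stage is validated, with ground truth attached.

A cohort is a full factorial of organ × strain × sex × age × replicate
(default 7 × 2 × 2 × 5 × 5 = 700 samples, ages 3, 6, 12, 18, 24 months). A
gene's value is the sum of

* one random intercept per factor level, drawn once per gene × level with
  standard deviation $\sqrt{f}$ for target variance fraction $f$ — realized
  fractions are *audited* (balanced ANOVA decomposition), not forced, which
  keeps samples exchangeable within design cells;
* a planted age trajectory: one of four archetypes (monotone up, monotone
  down, a turn-around after the second age, and a sharp adolescent peak with
  a primary decline by midlife), each zero-mean with unit maximum amplitude,
  scaled by a global amplitude and sign-flipped for the `B` half of an
  antiparallel twin pair;
* for regulator targets, a linear-plus-threshold function
  $e \cdot (0.6 z + \max(z - 0.5, 0))$ of the regulator's standardized
  realized values — nonlinear, so forest importance has a structural
  advantage over linear screens, and one-way, because the regulator itself is
  finalized before its targets are written;
* Gaussian noise with $\sigma = \sqrt{1 - \sum f}$ by default.

The default variance fractions follow the dominance hierarchy of multi-organ
cohorts (organ 0.873, strain 0.0274, sex 0.0031), and the default archetype
amplitude of 0.2 places the total age contribution near half a percent of
variance — small enough to be realistic, large enough to be recoverable
after harmonization. Values live on a z-like scale; an optional
exponentiation produces a nonnegative FPKM-like scale, which is the mode
where correction order genuinely matters (see below).

What the generator does *not* emulate: count-level sampling noise and
mean-variance coupling, organ-specific age trajectories, within-cell
replicate correlation (replicates are exchangeable by design), and real gene
identifiers. Passing tests therefore demonstrate correctness of the
machinery and recoverability of planted structure at desk scale — not
biological validity on any particular real data set.

## Harmonization and PVCA

`zscore_within` standardizes each gene to mean zero and unit *population*
variance inside each group; constant genes map to zero rather than NaN.
`combat_eb` wraps the parametric empirical-Bayes batch adjustment (no
covariate preservation term); genes with essentially no within-batch
variance bypass the fit unchanged. Age is never corrected. With nesting on
(the default), step $k$ is fitted separately within every stratum of the
covariates from steps $1..k{-}1$ — the "consecutively fitted subgroups"
convention; a flat mode exists for comparison.

PVCA standardizes genes, takes principal components of the sample space up
to a cumulative-variance threshold (default 0.6; at least two PCs), fits one
random intercept per design factor to every retained PC score
(main effects only, `lme4`), clamps negative estimates, and averages the
per-PC variance-component proportions with eigenvalue weights. Two numerical
choices matter:

* when a PC is perfectly explained by the design (zero residual), the mixed
  model likelihood is degenerate and the component split arbitrary — the
  implementation then falls back to the exact balanced-ANOVA decomposition;
* the retention threshold trades focus for coverage: 0.6 concentrates on the
  dominant factor's subspace (appropriate for *ranking* correction plans by
  their age fraction), while fraction-*recovery* studies use 0.9 so that the
  minor factors' directions are inside the retained subspace at all.

`search_order` enumerates all permutations of up to four covariates crossed
with per-step method assignments, ranks by the corrected matrix's PVCA age
fraction, and breaks ties by fewer ComBat steps, then lexicographically. On
the additive z-scale a fully nested correction of a balanced factorial is
essentially order-symmetric; the order becomes consequential on the
FPKM-like scale, where the dominant factor acts multiplicatively and
correcting it first removes the dominant distortion before the later fits —
this is exactly the constructed condition under which the order-search test
expects the organ-first plan to win.

## The selection engine

Defaults: 500 trees, up to 100 comparison runs, `alpha` 0.01 with Bonferroni
correction over the still-undecided attributes, 30 iterations, hit-set
threshold "nonrejected in ≥ 1 iteration". Importance is permutation
importance scaled to a Z-like score; an impurity mode is a fast fallback.
Forests run single-threaded with derived seeds, so every result is
reproducible and independent of execution order. Rejected features leave
the model between runs; confirmed features remain, since they keep shaping
multivariate importance. At least five shadow columns are always present so
the max-shadow reference stays stable for small feature sets.

Prediction quality is reported as cross-validated accuracy and Cohen's
kappa; in numeric mode the regression predictions are snapped to the nearest
design age before scoring (the discretization that makes kappa well-defined
for a numeric target). Folds are stratified by age level.

One power consideration is documented rather than hidden: a product
$f_2 f_3$ of two *independent* features gives every single tree split zero
expected gain (no marginal effect), which is a structural blind spot of
forest split selection. The recovery experiment therefore plants the
interacting pair as co-expressed ($\rho = 0.5$), as interacting transcripts
are; the product still has exactly zero linear correlation with the
response (odd moments vanish), so the planted signal remains invisible to
bivariate linear screening while being recoverable by the forest.

## Co-expression modules

The module stage works on the hit set: unsigned adjacency
$a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$, with $\beta$ the smallest power
whose scale-free fit index exceeds 0.94 (the index is the signed $R^2$ of
the binned log-log connectivity regression; when no power reaches the
threshold the best one is used and flagged). The adjacency is converted to a
topological-overlap dissimilarity, clustered by average linkage and cut at a
static height. By default the cut is scanned from just under the top merge
down through the gaps between successive merge heights until at least two
sufficiently large modules emerge — co-expression trees over weakly
correlated hit sets are nearly flat, so fixed fractions of the maximal
height would land outside the informative band. Clusters under the minimum
size become "grey". Each module is summarized by its eigengene — the first
principal component of the module's standardized expression, unit variance,
sign aligned with the module's mean profile so the pipeline is deterministic
— and by its mean signed pairwise correlation, the "average number of
correlations" statistic.

Because the network is unsigned, one module can contain mutually inverted
trajectories. `split_antiparallel` clusters module members by the
correlation distance of their *age-profile summaries* (per-age medians,
pooling organs/strains/sexes), cuts at distance 0.22, and flags the module
antiparallel when the two largest subgroups' mean profiles correlate below
−0.5. Applying the threshold to age-summarized profiles (not raw samples) is
a declared convention: it makes 0.22 act on trajectory shape.

## The directed network

`crossboruta` derives one selection per target with a seed hashed from the
master seed and the target's name, making results identical whatever the
execution order (and trivially parallelizable). Nonrejected features become
directed edges carrying iteration-averaged `meanImp`/`normHits`; an edge is
`confirmed` when confirmed in a majority of its nonrejected iterations —
a declared convention, since only the averages are otherwise defined.
`restrict_to_hits` keeps edges between hit genes (isolated hits remain as
nodes) and computes per node: AAS (with sentinels as above), the hub score
(number of distinct targets that selected the node, optionally
confirmed-only), and closeness centrality — per connected component,
$c(i) = (n_c - 1) / \sum_j d(i,j)$, isolated nodes 0, unweighted and
undirected by default with an inverse-`meanImp` weighted variant available.
Quantile thresholds (e.g. the 90% closeness cut) use the
linear-interpolation convention. GraphML export encodes numeric attributes
as 17-digit strings so the companion reader round-trips bit-exactly; the
undefined AAS travels as the string `"no value"`.

## Problem sizes and test design

All validation runs at desk scale, chosen as the package's own study
conditions: cohorts of 200–500 genes over 80–400 samples; null
family-wise-error control on 200 × 100 all-noise frames over 50 seeded
repetitions; recovery of {f1, f2, f3} over 20 seeds; selection-utility
comparisons on ~300 genes × 400 samples over 10 seeds; antiparallel and
regulator-hierarchy recovery over 20 seeds; exact brute-force oracles for
AAS (toy graphs ≤ 6 nodes) and closeness (random graphs ≤ 50 nodes). The
fraction-recovery and dominance-ordering cohorts plant fractions at
magnitudes a desk-scale estimator can resolve ({0.6, 0.1, 0.1} and
{0.55, 0.2, 0.12, 0.03}); the generator's *defaults* keep the realistic
hierarchy, whose finest distinction (sex at 0.31% vs age at 0.26% of
variance) is below any desk-scale resolution and is not asserted.

## Known limitations

* The selection engine's decisions are version- and setting-sensitive (tree
  count, run cap, alpha); hit counts should be read as reproducible under a
  fixed configuration, not as universal constants.
* PVCA with main effects only cannot attribute interaction variance; it
  lands in the residual.
* ComBat is parametric-prior only; no nonparametric mode, no surrogate
  variables.
* The module stage uses a static tree cut; dynamic cutting can be emulated
  by passing explicit cut heights.
* CrossBoruta edge decisions aggregate by majority; alternative aggregations
  (e.g. any-confirmed) are a one-line change on the stored per-iteration
  decision matrix.
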