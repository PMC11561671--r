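# crossage

Age-associated transcript selection and directed gene–gene association
networks for multi-organ aging transcriptomes.

## The problem

In a factorial aging cohort — several organs, two mouse strains, both sexes,
five ages across the lifespan — the variance hierarchy of bulk expression is
brutal: organ dominates by two orders of magnitude, and age is the smallest
factor of all. `crossage` implements an analysis stack for exactly this
regime:

* **Harmonization with an optimized correction order.** Nuisance covariates
  (organ, strain, sex) are removed step by step — within-group z-scoring or
  empirical-Bayes batch adjustment (ComBat), each step fitted within strata
  of the previously corrected covariates. All permutations of covariates and
  methods are ranked by the age variance fraction under principal variance
  component analysis (PVCA), and the best plan wins.
* **Shadow-feature random-forest selection (Boruta-style).** Every feature
  competes against its own permuted shadow copy inside a random forest; hit
  counts are classified by a Bonferroni-corrected binomial test into
  confirmed / tentative / rejected. The selection is iterated with
  independent seeds; a transcript is a *hit* when it is nonrejected in at
  least one iteration, with association strength `meanImp` (iteration-mean
  importance) and stability `normHits` (iteration-mean hit rate). Age is
  analyzed numerically (NVA) and categorically (CVA); hits are unioned.
* **Unsigned co-expression modules** over the hits: soft power chosen by the
  scale-free fit index, topological-overlap clustering, module eigengenes,
  and a hierarchical-clustering split (distance threshold 0.22 on age-profile
  correlation distance) that exposes *antiparallel* trajectory pairs hiding
  inside unsigned modules.
* **CrossBoruta and the asymmetric association strength (AAS).** The
  selection is re-run with every transcript in turn as the target, yielding
  a directed edge table target → selected feature. Per transcript
  *i*,

  $$\mathrm{AAS}(i) = \frac{\sum_{\text{edges where } i \text{ is the feature}} \mathrm{meanImp}}{\sum_{\text{edges where } i \text{ is the target}} \mathrm{meanImp}},$$

  so log₂ AAS > 0 marks transcripts that many others depend on while they
  depend on few — candidate hierarchically superior regulators. Hub scores
  (how many targets selected a transcript) and closeness centrality (with
  its 90%-quantile cut) complete the node metrics; networks export to
  GraphML/TSV.
* **A synthetic cohort generator** reproducing the design (organ ≫ residual
  > strain > sex > age variance hierarchy, four age-trajectory archetypes
  with antiparallel twins, planted nonlinear regulator → target
  dependencies) with ground truth, so every stage is validated by
  parameter-recovery tests.

## Worked example

```r
library(crossage)

config <- pipeline_config(
  design = cohort_design(organs = paste0("O", 1:4), strains = c("B6", "D2"),
                         sexes = c("F", "M"), ages = c(3, 6, 12, 18, 24),
                         replicates_per_cell = 3, seed = 1),
  structure = default_planted_structure(300),
  boruta = boruta_config(n_trees = 150, max_runs = 20, n_iterations = 3, seed = 1),
  crossboruta_config = boruta_config(n_trees = 100, max_runs = 15,
                                     n_iterations = 1, seed = 1),
  min_module_size = 8, eval_folds = 5, seed = 1)
report <- run_pipeline(config)
print(report)
```

```
pipeline_report (seed 1): 300 genes x 240 samples
  best plan: combat(sex)->zscore(strain)->combat(organ) (of 48 evaluated); PVCA age fraction 0.0001 -> 0.0765
  hits: NVA 45, CVA 20, union 51 (overlap 14)
  age prediction accuracy: all features 0.338 (kappa 0.172), hit set 0.421 (kappa 0.276)
  modules: 2 (power 6, 2 antiparallel); network: 90 edges among hits
```

Reading the report: on the raw matrix age explains ~0.01% of variance
(organ ~99.8%); the winning correction plan lifts the PVCA age fraction to
~7.6%. Of 300 genes, 51 are selected as age hits (45 numeric-age, 20
categorical-age, 14 by both). Restricting the age predictor to the hit set
raises cross-validated accuracy from 0.34 to 0.42 — the selection-utility
signature. The hits decompose into unsigned co-expression modules, one of
which splits into antiparallel trajectory subgroups, and the CrossBoruta
stage yields the directed aging network among the hits, whose node metrics
(AAS, hub score, closeness) are written alongside the GraphML export when
`out_dir` is set.

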