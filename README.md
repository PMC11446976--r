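# proteoSubtype

Proteogenomic subtyping of never-smoker lung adenocarcinoma (NSLA) without
*EGFR*/*ALK* driver alterations — as a tested, reusable R pipeline.

Patients with driver-negative NSLA have no targeted-therapy option and
respond poorly to immune checkpoint inhibitors, yet their tumours are far
from homogeneous. Joint RNA + protein signature profiling stratifies such
cohorts into four molecular subgroups with distinct prognosis:
proliferation-high (**P**, worst outcome), immune-high (**I**, best
outcome), angiogenesis-high (**A**) and metabolism-high (**M**).
`proteoSubtype` implements that classification and the surrounding
integrative analyses, and ships a fully labelled synthetic-cohort generator
so every stage is testable without access-controlled patient data.

## What it computes

* **Signature scoring** — single-sample GSEA with the rank-weighted
  running-sum statistic. For sample *s* and gene set *G*, genes are ranked
  by decreasing expression and

  ES(G, s) = Σᵢ [ P_in^w(i) − P_out(i) ],

  where P_in^w is the weighted in-set ECDF with weights |rank|^α
  (α = 0.25 by default) and P_out the complement ECDF. ESTIMATE-style
  immune/stromal scores are the unnormalised scores of two dedicated sets.
* **Cascaded classification** — RNA and protein enrichment matrices are
  row-z-scored and stacked; samples at or above the cohort Q3 of the
  proliferation signature become **P**; among the rest, T-cell-signature-high
  samples become **I**; the remainder is split in two by complete-linkage
  clustering (Euclidean), the higher mean angiogenesis cluster becoming
  **A**, the other **M**. A single-cut four-group mode is also provided.
* **Genomic integration** — per-gene cis CNA–RNA and CNA–protein Pearson
  correlations with P < 0.05 / P < 0.01 tiers, trans effects of a chosen
  effector, mutation–subgroup Fisher tests, mutation co-occurrence, TMB,
  and carrier-vs-non-carrier proteome shifts (Welch + BH).
* **CGA outliers** — cancer-germline antigens called when expression is
  ≥ 100-fold above and > 3 SD above the cohort leave-one-out mean on the
  linear FPKM scale, plus subgroup composition tests.
* **Protein networks** — variance + correlation protein selection,
  complete-linkage co-expression modules with hypergeometric annotation,
  and k-core graph filtering.
* **Survival** — Kaplan–Meier curves, multi-group log-rank, multivariate
  Cox (sex, age, ordinal stage, subtype; Efron ties; HRs vs subgroup I).
* **Synthetic cohorts** — 102 samples (3 planted below the 0.4 purity
  cutoff), 5000 genes, four latent subgroups with +1.5 log2 signature
  shifts, an attenuated protein layer (r ≈ 0.6, 20 % genes missing),
  300 cis dosage genes (β = 0.8), TP53-like mutation enrichment (48 % in P),
  subgroup hazard ratios 2.9 / 2.0 / 1.4 vs I, ~40 % censoring, and 10
  planted CGA-outlier samples — with the ground truth attached.

## Worked example

```r
library(proteoSubtype)

cfg    <- simulationConfig(seed = 1)
cohort <- applyPurityFilter(generateCohort(cfg))$bundle
cohort
#> CohortBundle: 99 samples | rna 5000 genes, protein 4000, cna 5000 |
#>   1050 mutations | 32 gene sets | synthetic (truth attached)

sets <- geneSets(cohort)
sig  <- sets[setdiff(names(sets), "cga_candidates")]
es   <- combineLayers(ssgseaScore(cohort@rna, sig),
                      ssgseaScore(cohort@protein, sig))
subtypes <- classifyCascade(es)
subtypes
#> SubtypeAssignment [cascade]: P=25 I=28 A=20 M=26

adjustedRand(subtypeLabels(subtypes), cohort@truth$labels)
#> [1] 0.9722101

clin <- cohort@clinical
lab  <- subtypeLabels(subtypes)[clin$sample]
logrankTest(clin$os_time_months, clin$os_event, lab)$p
#> [1] 0.001182013

det <- cgaDetect(toLinearFpkm(cohort@rna), sets$cga_candidates)
sum(det$positive)
#> [1] 10
```

The classifier recovers the planted subgroups almost perfectly
(ARI 0.97), the four recovered subgroups separate survival
(log-rank p ≈ 0.001), and all 10 planted CGA-outlier samples are found.
At n = 99 the per-subgroup Cox hazard ratios are noisy; the acceptance
script re-estimates them on a large simulated cohort where the partial
likelihood is tight.

The whole chain is also available as one call
(`runPipeline(list(seed = 1, outDir = "run"))`) writing every table plus a
hash-manifested `run_summary.json`, and as a thin command line
(`inst/scripts/proteosubtype.R` with `simulate | score | classify |
run-all`).

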