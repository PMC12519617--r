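# quadstrat

Quadrant stratification of plasma-proteomics cohorts by systemic
inflammation and neurofilament light chain (NEFL).

Inflammation and neuro-axonal injury are distinct processes in epilepsy and
do not always co-occur. `quadstrat` is an R package for asking, from
Olink-style plasma proteomics (NPX, log2-scale relative abundance), *which
patients show which process* — and how seizure burden and drug resistance
distribute across the resulting strata. It is aimed at researchers working
with blood-biomarker panels in epilepsy or other neurological cohorts who
want a reproducible, tested implementation of this stratification and its
statistical battery.

## What it computes

1. **Ingest** — merge multi-panel long-format NPX exports, resolving
   assays duplicated across panels by highest geometric-mean expression
   (equivalently highest mean NPX), and drop assays failing batch-release
   QC.
2. **Composite pro-inflammatory score** — per-protein Z-scores
   `Z = (NPX − mean) / SD` over the full cohort for 12 literature-selected
   pro-inflammatory proteins (CASP1, CCL11, CCL2, CCL3, CXCL8, IFNG, IL17A,
   IL18, IL1B, IL2, IL6, TNF), summed per patient:
   `PI_score = Σⱼ Zⱼ`.
3. **Quadrants** — NEFL is "high" above 0.5 NPX (the 10 pg/mL abnormality
   threshold for ages 18–50); the composite score is banded at its 40th and
   60th percentiles, excluding the ambiguous central 20%; crossing the two
   gives High-Low, High-High, Normal-High, Normal-Low.
4. **Association battery** — Pearson chi-square (no continuity correction)
   on quadrant×category tables with pairwise Benjamini–Hochberg post hoc
   tests; Kruskal–Wallis with Dunn–Bonferroni post hoc for continuous
   variables; Spearman correlation matrices with the |r| > 0.1 & p < 0.05
   highlight rule.
5. **Correspondence analysis** — SVD of the standardized residual matrix,
   both rows and columns in principal coordinates (symmetric map), and
   Euclidean quadrant-to-category distances in the first two dimensions.
6. **Differential expression** — per-protein Welch t tests between two
   quadrants, log2 fold change as the difference of mean NPX, BH-FDR, and
   the triple significance rule (FDR < 0.05, p < 0.05, |log2FC| ≥ 1), with
   volcano-plot coordinates.
7. **Synthetic cohorts** — a generator with the study's marginal
   distributions, a latent-factor pro-inflammatory block, tunable
   NEFL–score coupling, planted blood–brain-barrier protein shifts and
   outcome enrichment, so the whole pipeline is testable without access to
   patient-level data. The published quadrant-by-category contingency
   tables ship as packaged fixtures.

## Worked example

```r
library(quadstrat)

# a 176-patient synthetic cohort with the default study conditions
report <- run_pipeline(pipeline_config(simulate = synthetic_params(seed = 7)))
report
#> <analysis_report>
#>   quadrant counts: High-Low=10, High-High=10, Normal-High=60, Normal-Low=60, unclassified=36
#>   chi-square seizure_status  X2 =  12.17, df = 6, p = 0.058
#>   chi-square epilepsy_type   X2 =   3.67, df = 6, p = 0.722
#>   chi-square gender          X2 =   4.77, df = 3, p = 0.189
#>   chi-square epilepsy_status X2 =  21.10, df = 6, p = 0.002
#>   chi-square n_asm           X2 =  25.56, df = 15, p = 0.043
#>   chi-square freq_bin        X2 =  11.88, df = 6, p = 0.065
#>   diffexp High-High vs Normal-Low: 10 significant (11 relaxed)
```

36 of 176 patients (20%) fall in the excluded central band of the composite
score. In this seed the quadrant×epilepsy-status association is significant
(p = 0.002): the generator plants four-fold odds of recent seizures and
multi-drug treatment in the latent High-High stratum, and the pipeline
recovers the resulting drug-resistance enrichment. The differential
expression between High-High and Normal-Low flags the three planted
blood–brain-barrier proteins (MMP1, VEGFA, HGF) among its significant hits.

Validation against the published summary tables:

```r
fv <- run_fixture_validation()
sapply(fv$chi_square, function(x) round(x$statistic, 2))
#>  seizure_status   epilepsy_type          gender epilepsy_status           n_asm
#>           12.34            2.14            5.85           13.47           27.10

round(fv$ca_distances$epilepsy_status, 2)
#>              DRE undetermined  WCE
#> High-Low    0.48         0.30 0.28
#> High-High   0.24         0.86 0.98
#> Normal-High 0.63         0.01 0.21
#> Normal-Low  0.66         0.16 0.08
```

The High-High quadrant sits closest to drug-resistant epilepsy (distance
0.24) and farthest from well-controlled epilepsy (0.98); the Normal-Low
quadrant is nearest the seizure-free category (0.07 in the seizure-status
map). Shorter distances indicate stronger quadrant–category association.

## Documentation

See the vignette (`vignettes/quadrant-stratification.Rmd`) for the model,
its assumptions, the synthetic-cohort design, numerical choices, and known
limitations.
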