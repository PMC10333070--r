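# wmscore

Cross-talk between RNA-modification pathways shapes tumour biology: the
enzymes that deposit m6A and m1A methyl marks, the 3'-end processing factors
that choose alternative polyadenylation (APA) sites, and the ADAR deaminases
that perform A-to-I editing — 26 "writer" enzymes in all — are co-regulated
in gastric cancer, and their joint expression patterns track the tumour
microenvironment (TME) and patient prognosis. `wmscore` implements the full
analysis that turns a bulk expression cohort into a per-patient prognostic
score built on those patterns:

1. **Pattern discovery** — resampling-based consensus clustering
   (Monti-style) of the 26-writer expression panel, with the number of
   clusters chosen by the PAC criterion (proportion of ambiguous
   clustering, the consensus-CDF mass between 0.1 and 0.9) refined by the
   consensus-CDF delta-area elbow.
2. **Pattern-discriminating genes** — an empirical-Bayes moderated t-test
   (gene variances shrunk toward a scaled-F prior fitted by moments with
   trigamma inversion) contrasts the best-prognosis cluster against each
   other cluster; genes with p ≤ 0.005 in *every* contrast form the DEG
   signature.
3. **WM_Score** — the DEG rows are z-scored and decomposed by SVD; each
   patient's score is the sum of the first two principal-component
   coordinates, `WM_Score_i = PC1_i + PC2_i`, oriented so higher scores
   carry higher hazard.
4. **Dichotomization** — a maximally selected log-rank scan over all
   feasible cutpoints (≥ 10% of patients per side) splits the cohort into
   high and low score groups.
5. **Associations** — Kaplan–Meier curves and log-rank tests, univariate
   Cox hazard ratios, cumulative/dynamic time-dependent ROC AUCs at the
   5/6/7-year horizons, single-sample enrichment (ssGSEA, a GSVA-style
   variant, and ESTIMATE-style immune/stromal composites), tumour
   mutational burden, and pairwise mutation co-occurrence by Fisher's
   exact test.

Because the original cohorts are external, the package ships a
synthetic-cohort generator (`simulate_cohort()`) that emulates their
statistical structure — four latent writer patterns, pattern-tied DEG
blocks, proportional-hazards survival driven by a latent score, and a
sparse mutation layer with one planted co-occurring pair — so the entire
pipeline is testable end to end against known ground truth.

## Worked example

```r
library(wmscore)

co  <- simulate_cohort(cohort_config(seed = 7))
rep <- run_wm_pipeline(co, n_iter = 100, seed = 11)
rep
#> <wm_report> k = 4 (PAC-selected), reference cluster 3, 165 DEGs
#>   cutpoint -0.205 (306 high / 94 low), log-rank p = 5.39e-20, HR/SD = 2.06
#>   AUC: 0.725 @ 60m, 0.781 @ 72m, 0.821 @ 84m
```

Reading the report: the consensus sweep selected `k = 4` writer patterns
(matching the four planted ones — `mclust::adjustedRandIndex` against the
truth is 0.99 here); cluster 3 had the best Kaplan–Meier median survival
and became the reference for the DEG contrasts, which intersected to 165
genes; the maximally selected cutpoint splits patients 305/95, the high
WM_Score group has strongly worse survival (log-rank p ≈ 5e-20, hazard
ratio ≈ 2.1 per score SD), and the score discriminates 5-year survival
with AUC 0.73. The recovered score tracks the planted latent risk score at
Spearman ρ ≈ 0.99.

Every stage is also exposed on its own — `writer_registry()`,
`consensus_sweep()` / `select_k()`, `moderated_t_test()` /
`intersect_degs()`, `compute_wm_score()` / `optimal_cutpoint()`,
`ssgsea_scores()` / `gsva_scores()` / `estimate_scores()`,
`km_estimate()` / `logrank_test()` / `cox_univariate()` /
`time_dependent_auc()`, `mutation_frequency()` / `compute_tmb()` /
`cooccurrence_fisher()` — and returns tibbles (or objects with `tidy()` /
`glance()` methods), so results chain with the pipe. `autoplot()`,
`plot_consensus_cdf()` and `plot_km_curves()` give quick ggplot2 views.

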