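---
title: "Methods: writer-pattern discovery and WM_Score construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: writer-pattern discovery and WM_Score construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wmscore` quantifies how the joint expression of 26 RNA-modification
"writer" enzymes — 7 m6A methyltransferase-complex members, 4 m1A
methyltransferases, 12 alternative-polyadenylation 3'-end processing
factors, and 3 A-to-I editing deaminases — stratifies a tumour cohort,
and condenses the stratification into a per-patient prognostic score.
This vignette is the package's own account of each modelling step, the
tunable parameters, the synthetic cohort the tests run against, and the
numerical conventions.

## The pipeline model

**Input.** A genes × samples matrix of log-scale expression (microarray
log2 intensities or log-transformed RNA-seq), a clinical table with
right-censored overall survival in months, and optionally a MAF-lite
mutation table and GMT gene sets. Gene symbols are uppercased at
ingestion and matched by exact string equality; duplicate gene rows are
collapsed by keeping the row with the highest mean expression, the usual
microarray probe-collapse convention (how the original platforms were
collapsed is not knowable from the data, so the rule is a documented
convention, not a claim).

**Consensus clustering.** Samples are clustered on the z-scored writer
panel (per-gene z-scoring, because writer expression scales differ across
genes and an unscaled distance would be dominated by the most variable
writers). Each of `n_iter` iterations subsamples 80% of samples without
replacement, computes 1 − Pearson correlation distances, and cuts an
average-linkage dendrogram at k. The consensus index of a sample pair is
its co-clustering frequency among co-sampled iterations; final labels cut
an average-linkage tree on 1 − consensus and are renumbered by descending
cluster size. k-means is available as an alternative base clusterer.

**Choosing k.** The proportion of ambiguous clustering,
PAC(k) = CDF(0.9) − CDF(0.1) over upper-triangle consensus indices, is
the primary stability criterion. Plain argmin-PAC is not identifiable
when clusters are nested: a coarse split of a genuinely finer structure
can be exactly as stable as the true one, driving PAC to ~0 at several k
at once. `select_k()` therefore treats every k within `pac_tol` (0.01) of
the minimal PAC as tied, and among the tied candidates picks the largest
k whose relative gain in consensus-CDF area (`delta_area`) is at least
`min_gain` (0.05) — the classic delta-area elbow. When no candidate shows
a real gain the smallest tied k wins, so exact ties without stability
gains resolve toward parsimony.

**Differential expression.** The reference cluster is the one with the
best Kaplan–Meier median survival (medians undefined because the curve
never reaches 0.5 count as best; this automates what would otherwise be a
hand-picked "good-prognosis" cluster). It is contrasted against each
other cluster with a moderated two-group t-test: gene-wise residual
variances are shrunk to
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ with the prior
$(d_0, s_0^2)$ fitted by method of moments on $\log s_g^2$ (scaled-F
model; the trigamma equation is inverted by Newton iteration to a 1e-8
relative step tolerance). The moderated t is referred to a t distribution
on $d_0 + d_g$ degrees of freedom. `d0 = 0` reproduces the ordinary
equal-variance t-test and `d0 = Inf` a fixed-variance z-test; both limits
are exposed and asserted numerically in the tests. The DEG signature is
the intersection of genes with raw p ≤ 0.005 (the threshold is inclusive)
in *all* contrasts; raw rather than adjusted p is the default because
that is the convention this score construction follows, with BH-adjusted
selection available by flag.

**Scoring.** DEG rows are z-scored and the samples × genes matrix is
decomposed by SVD. The score is the sum of the first two
principal-component coordinates, `WM_Score = PC1 + PC2`. Two sign
conventions matter:

* *Per component*: a principal component's sign is arbitrary. It is fixed
  so the **sum of gene loadings is positive** (majority direction). We do
  not anchor on the single largest loading: the DEG intersection
  legitimately contains genes anti-correlated with the dominant block
  (e.g. writers suppressed in the reference pattern), and whichever gene
  happens to carry the largest loading can flip the component under small
  changes to the gene set, scrambling PC1 + PC2.
* *Overall*: the pipeline then orients the whole score so that a
  univariate Cox fit on it has positive log hazard ratio — "high score =
  worse prognosis", matching the score's intended clinical semantics.

Constant DEG rows are dropped with a warning; a standardized matrix of
rank < 2 is an error (PC2 would be meaningless).

**Dichotomization.** `optimal_cutpoint()` scans every distinct score
value whose split leaves at least `minprop` (default 0.1) of the cohort
on each side and maximizes the absolute standardized log-rank statistic
(ties toward the smaller cut). The selected statistic is maximally
selected and therefore optimistically biased; the package documents this
(and the tests demonstrate the inflation under a null) but applies no
correction, because the cut is used only to define groups — confirmatory
p-values should come from independent data.

**Associations.** Kaplan–Meier estimation, the log-rank test and Cox
regression delegate to the survival package (Breslow ties by default,
Efron optional; Newton–Raphson tolerance 1e-9, 50 iterations). The
time-dependent AUC is the Kaplan–Meier-based cumulative/dynamic
estimator: at horizon t and cutoff c,
Sens = (1 − S(t|M>c))·P(M>c)/(1 − S(t)) and
Spec = S(t|M≤c)·P(M≤c)/S(t) with subgroup KM curves; the ROC is traversed
in cutoff-sweep order (sorting by FPR is numerically fragile because the
KM-based rates carry floating-point noise) and integrated by trapezoid.
Horizons follow the months convention: five/six/seven years are 60/72/84
months. Without censoring the estimator reduces exactly to the binary AUC
with cases T ≤ t, which the tests assert. Group comparisons (Wilcoxon,
Kruskal–Wallis) and correlations (Pearson, midrank Spearman) wrap the
standard stats routines.

**Enrichment.** `ssgsea_scores()` implements the single-sample
running-sum statistic: genes are ordered by decreasing expression within
a sample and the score is the integral of the weighted in-set ECDF
(weights rank^τ, τ = 0.25, the method's canonical exponent) minus the
uniform out-of-set ECDF. Scores are globally range-normalized by default;
the ESTIMATE-style composites use unnormalized scores and report
immune + stromal as the combined score (the platform-specific
tumour-purity calibration is deliberately out of scope). Ties are broken
by a deterministic 1e-9 × gene-index perturbation, so results are
reproducible and still rank-invariant. `gsva_scores()` estimates each
gene's expression CDF across samples with a Gaussian kernel (bandwidth =
SD/4), ranks the CDF values within a sample, and walks the ranked list
with the symmetric rank statistic as in-set weight; `mx_diff` selects
between the sum of the two extreme deviations and the single largest
deviation. Published TME cell-type signatures are not redistributable, so
enrichment is exercised on planted synthetic signatures; real signature
GMTs are supplied by the user.

**Mutations.** The binary mutation matrix counts non-silent classes
(everything except silent/intronic/UTR — the vocabulary is configurable
since TMB definitions vary). Co-occurrence testing applies a two-sided
Fisher exact test per gene pair (genes mutated in ≥ 3 samples), reports
the sample odds ratio with a Haldane 0.5 correction when a cell is zero,
and labels pairs co-occurring/exclusive at BH q < 0.05.

## The synthetic cohort

`simulate_cohort()` generates the study conditions the tests and the
acceptance script run under. Defaults (all on the log2 scale, noise SD 1):

* **400 samples** in four latent patterns at proportions
  0.31/0.29/0.20/0.20, echoing the 329/308/204/210 split reported for a
  ~1,050-patient merged cohort at desk scale.
* **Writer signatures**: each pattern shifts one modification-class block
  up and another down by ±1.5 (pattern 1: m6A+/m1A−; 2: APA+/AtoI−;
  3: m1A+/m6A−; 4: AtoI+/APA−). The ± structure keeps the four profiles
  mutually non-collinear — necessary because correlation distance centres
  each sample's profile, so a uniformly shifted ("flat") signature would
  be invisible. A 1.5 log2-fold shift is a realistic magnitude for
  subtype-defining regulators on arrays.
* **DEG blocks**: 150 genes per pattern shifted +1.0 within their pattern;
  1,500 unstructured background genes. The reference (immune) block's
  second half is additionally shifted −1.0 in the stromal pattern
  (pattern 2), mirroring the suppression of immune-activation genes under
  stromal activation. This second axis matters: the three-contrast DEG
  intersection isolates the reference block, and if that block carried
  only one signal direction PC2 would be pure noise and a PC1 + PC2 score
  could never be recovered stably.
* **Latent score and survival**: the true score is the standardized
  PC1 + PC2 of the reference block, oriented so the immune pattern scores
  lowest (good prognosis). Event times are Weibull (shape 1.2, scale 60
  months — median survival around four years, typical of advanced gastric
  cancer cohorts) with hazard multiplier exp(0.8 · score); censoring is an
  independent exponential whose rate is solved by `uniroot` so the
  expected censored fraction is 0.3.
* **Mutations**: writers mutate independently at 0.012 (so about a
  quarter of samples carry a background panel mutation), except the
  planted pair CSTF3/RBM15 with 0.08 marginals and odds ratio 8, drawn
  from the exact 2×2 distribution with those margins. Non-silent classes
  are drawn 60/20/10/10 missense/frameshift-del/nonsense/splice-site
  (missense and frameshift deletions predominate in this tumour type),
  plus a thin independent silent layer to exercise the TMB split.

A single master seed drives every stage through fixed per-stage offsets
(R's Mersenne-Twister), so cohorts are bit-reproducible.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: platform/batch effects and probe-level
artifacts, correlated background genes, non-proportional hazards or
informative censoring, copy-number/methylation layers, and real TME
signature geometry. Recovery statistics on this cohort (ARI ≈ 1, score
correlation ≈ 0.99) characterize correctness of the machinery under the
planted model, not expected performance on clinical cohorts, where the
published analyses report far more modest discrimination (AUCs near
0.6).

## Problem sizes and numerical choices

The test-suite and acceptance runs use 400-sample cohorts (200 for the
cheaper smoke tests), 100 consensus iterations per k over k = 2..6, a
10,000-relabeling permutation oracle for the log-rank test at n = 20, and
a 500-sample Cox recovery check — sizes chosen so the whole suite runs in
a couple of minutes while keeping Monte-Carlo noise well below the
asserted tolerances. Note that the asymptotic log-rank p and its
permutation reference are compared within 0.05 rather than within pure
Monte-Carlo error: at ~16 events the chi-square approximation itself
carries error of order 0.02, which no implementation can beat.

Other conventions: scores exactly equal to the cutpoint go to the low
group (strict inequality for "high"); `select_k` ties resolve as
described above; BH adjustment and Fisher p-values come from `p.adjust`
and `fisher.test` (with p clamped at 1 against floating-point overshoot);
zero-variance genes are an error where a distance is required (consensus)
and are dropped with a warning where a decomposition can proceed without
them (scoring).

## Known limitations

* The maximally selected cutpoint statistic is not corrected for
  selection; its p-value must not be reported as confirmatory.
* Two-group DE contrasts only; general design matrices (covariates,
  batch) are out of scope.
* `estimate_scores()` returns enrichment composites, not calibrated
  tumour purity.
* A frozen-loadings projection across cohorts is not provided; like the
  original construction, the score is refit per cohort, so absolute score
  values are not comparable between cohorts — only within-cohort
  contrasts are meaningful.
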