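# nmrmetab

Untargeted ¹H-NMR tissue metabolomics in R: peak alignment, dual
(tissue/cellular) normalization, validated PLS-DA, effect-size/FDR
univariate screening, STOCSY, and metabolic-signature derivation.

## What it is for

Untargeted 1D ¹H-NMR of tissue extracts yields, per sample, an intensity
vector on a chemical-shift (ppm) axis in which each metabolite appears as
a set of multiplets. Turning a cohort of such spectra into a defensible
list of "metabolites that differ between groups" requires a chain of
statistical steps, each with pitfalls: chemical-shift drift must be
corrected (recursive segment-wise peak alignment, RSPA), the water band
excluded, intensities normalized — either to total spectral area (the
*tissue* signature) or to cell counts (the *cellular* signature, which
approximates intracellular concentration changes when groups differ in
cellularity) — and claims validated both multivariately (PLS-DA with
Monte Carlo cross-validation) and univariately (normality-routed tests,
standardized effect sizes with errors, FDR control).

`nmrmetab` implements that chain end to end for pairwise group
comparisons, plus the set operations that turn per-comparison results
into signatures: tissue/cellular signature pairs, condition-specific
signatures by intersection across comparisons, cellularity
classification, and stage-progression profiles. The motivating
application is a six-group murine pancreatic cohort (normal, acute
pancreatitis, and four cancer-progression stages); the package ships the
study's design and result tables as machine-readable fixtures and a
synthetic spectral-cohort generator with planted ground truth, so every
stage is testable without any external data.

## The core statistics

* **PLS-DA (NIPALS)** with a centred ±1 class response; per-variable
  importance `VIP_j = sqrt( p · Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a )`
  (mean VIP² = 1), and loadings back-transformed by the unit-variance
  scaling SDs for display on the intensity scale.
* **MCCV**: repeated stratified hold-out of 1/7 of each class, 500 runs;
  per run `Q² = 1 − PRESS/TSS` on held-out responses; pooled confusion
  matrix giving classification rate, sensitivity and specificity. Scaling
  is refit inside every training fold (no held-out leakage).
* **Univariate screen**: Shapiro–Wilk routes each window to Welch's *t*
  or the Wilcoxon rank-sum test; effect sizes are Hedges' *g* with
  standard error `sqrt((n_a+n_b)/(n_a n_b) + g²/(2(n_a+n_b−2)))`;
  Benjamini–Hochberg FDR across the window family. A window is
  *significant* when |ES| > SE and p < 0.05 — the same inclusion rule the
  study tables use.
* **RSPA**: bounded integer segment shifts maximizing FFT
  cross-correlation with the cohort median spectrum, applied recursively;
  a sample is only accepted if its correlation to the reference does not
  decrease.

## Worked example

Simulate a pancreatitis-vs-normal cohort (n = 6 vs 7, the study's sample
sizes) with five planted effects, then run the pipeline:

```r
library(nmrmetab)

eff <- data.frame(metabolite = c("Alanine","ATP","AMP","Formate","GSH"),
                  group = "Pt", log_fold = c(-0.9, 0.9, -0.9, -0.9, 0.9))
cfg <- simulation_config(groups = cohort_design()[1:2, ], effects = eff,
                         n_points = 2048, peak_width = 0.006, seed = 42)
cohort <- simulate_cohort(cfg)

m  <- exclude_region(cohort$matrix, 4.7, 5.0)   # water band
m  <- exclude_region(m, -0.03, 0.03)            # TSP reference
m  <- rspa_align(m)
ta <- normalize_spectra(m, "total_area")

fit <- fit_plsda(uv_scale(ta), n_components = 2)
#> PLS-DA: 2 component(s), classes N vs Pt, R2Y = 0.997

val <- mccv(ta, factor(ta$samples$group, levels = c("Pt", "N")),
            n_blocks = 7, n_runs = 500, seed = 42)
#> MCCV (7 blocks, 500 runs): Q2median = 0.719 | CR = 100.0% |
#>   sens = 100.0% | spec = 100.0% (positive: Pt)

screen <- compare_groups(
  integrate_windows(ta, assignment_table(cfg$panel)), "Pt", "N")
screen[screen$significant,
       c("metabolite", "es", "es_error", "p_value", "p_adjusted")]
#>  metabolite    es es_error  p_value p_adjusted
#>         GSH  5.21    1.242 7.80e-07   0.000039
#>     Alanine -4.87    1.178 1.17e-03   0.011655
#>         ATP  3.69    0.963 3.10e-04   0.003876
#>         AMP -3.46    0.923 2.33e-04   0.003876
#>     Formate -2.92    0.834 2.28e-04   0.003876
#>  Isoleucine  1.51    0.643 2.24e-02   0.186973
#>      Lysine -1.18    0.611 3.92e-02   0.279964
```

All five planted metabolites are recovered with the right sign and
survive FDR; the two extra windows are chance-level hits (their adjusted
p-values exceed 0.05). The near-perfect MCCV metrics reflect the strong
planted separation; on label-permuted data the same machinery returns
Q²median ≈ 0 and a ~50% classification rate.

The published study tables are available directly — for example the
10-metabolite pancreatitis signature emerges from the packaged tables by
intersection:

```r
t2 <- load_fixture("T2")
pairs <- list(
  build_signature_pair(fixture_comparison(t2, "Pt_vs_N",  "tissue"),
                       fixture_comparison(t2, "Pt_vs_N",  "cell")),
  build_signature_pair(fixture_comparison(t2, "Pt_vs_LG", "tissue"),
                       fixture_comparison(t2, "Pt_vs_LG", "cell")))
intersect_condition_signature(pairs, "Pt")
#> Pt-specific signature: 10 members
#>   up:   ADP, ATP, GSH, Phenylacetate
#>   down: Alanine, AMP, Formate, Niacinamide, TMAO, UMP
#>   excluded: GPC (FDR-nonsignificant); PC (direction conflict)
```

## Package layout

| | |
|---|---|
| `simulate_cohort()`, `default_panel()` | synthetic cohorts with planted effects |
| `read_spectra()`, `load_fixture()` | matrix-TSV / Bruker 1r input, packaged study tables |
| `to_common_grid()`, `exclude_region()`, `rspa_align()`, `normalize_spectra()`, `uv_scale()` | preprocessing |
| `fit_pca()`, `fit_plsda()`, `vip()`, `backtransform_loadings()`, `mccv()`, `stocsy()` | multivariate models |
| `integrate_windows()`, `compare_groups()`, `effect_size()`, `bh_adjust()` | univariate screen |
| `build_signature_pair()`, `intersect_condition_signature()`, `classify_cellularity()`, `progression_profile()` | signatures |
| `run_pipeline()` | end-to-end orchestration with a checksummed manifest |

The methods vignette (`vignettes/nmr-metabolomics-pipeline.Rmd`)
documents the models, parameter defaults and the design decisions in
detail.
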