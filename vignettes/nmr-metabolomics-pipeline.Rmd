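---
title: "Untargeted 1H-NMR tissue metabolomics with nmrmetab: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untargeted 1H-NMR tissue metabolomics with nmrmetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrmetab)
```

## The problem and the workflow

`nmrmetab` implements the statistical workflow used to extract metabolic
signatures from untargeted one-dimensional ^1^H-NMR spectra of tissue
extracts. The motivating application is a murine pancreatic study with six
groups — normal tissue (N), caerulein-induced acute pancreatitis (Pt), and
four stages of pancreatic cancer progression (low-grade PanIN lesions LG,
high-grade lesions HG, ductal adenocarcinoma PDA and its sarcomatoid
variant Sarc) — but every stage is generic 1D-NMR chemometrics:

1. interpolation onto a common chemical-shift grid and exclusion of the
   residual water band (4.7–5.0 ppm) and of the TSP reference resonance;
2. recursive segment-wise peak alignment (RSPA);
3. normalization, either to total spectral area (the *tissue* view) or to
   group-average cell counts (the *cellular* view);
4. unit-variance scaling, PCA and PLS-DA with VIP scores and
   back-transformed loadings, validated by Monte Carlo cross-validation
   (MCCV); STOCSY for assignment support;
5. integration of assigned peak windows and a univariate screen
   (Shapiro–Wilk-routed Student's *t* / Wilcoxon, Hedges' *g* with its
   standard error, Benjamini–Hochberg FDR);
6. set operations on the per-comparison results: tissue/cellular
   signature pairs, condition-specific signatures by intersection, and
   stage-trajectory profiles.

Because the raw cohort is not required for development or testing, the
package ships (a) machine-readable versions of the study's printed tables
(`load_fixture()`), which are the published end state of stage 5 and drive
exact end-to-end tests of stage 6, and (b) a synthetic spectral-cohort
generator (`simulate_cohort()`) that produces cohorts with the statistical
structure stages 1–5 assume, with known ground truth.

## The synthetic cohort generator

Each sample's spectrum is a sum of Lorentzian multiplets on a ppm grid.
For metabolite $m$ with group mean concentration
$\mu_{gm} = \mu_m e^{\beta_{gm}}$ (where $\beta_{gm}$ is the planted
natural-log fold change, zero in the reference group), the per-sample
concentration is drawn log-normally with coefficient of variation
`between_sample_cv`. A multiplet of relative intensity $r$ at centre
$\delta_0$ is rendered as $k$ lines (s/d/t/dd $\to$ 1/2/3/4 lines with
binomial weights, "m" $\to$ 5 equal lines) spaced by a J-coupling
surrogate (0.012 ppm $\approx$ 7 Hz at 600 MHz), each a unit-area
Lorentzian of half-width `peak_width`, shifted by a per-sample,
per-multiplet Gaussian jitter truncated at $\pm 3$ SD (emulating
pH-driven drift). On top of the metabolite signal the generator adds a
deterministic slowly varying baseline, a broad residual water hump at
4.85 ppm, i.i.d. Gaussian noise, and a TSP reference peak at 0.0 ppm
whose area is log-normal with CV `reference_peak_cv` — the reference
intensity in the emulated study varied too much for absolute
quantitation, and the generator reproduces that nuisance.

Intensities scale linearly with the sample's cell-count draw relative to
the reference group's average, except for metabolites listed in
`extracellular`; this is what makes the tissue-vs-cellular distinction
testable: a metabolite whose per-cell concentration is constant still
shows a tissue-level change wherever cellularity differs.

Key defaults, with reasons:

* **Groups** — the six study groups with $n = 7, 6, 5, 7, 6, 9$ and
  group-average cell counts 1761, 4454, 2794, 2422, 2318, 2958 (relative
  errors 19–29%), i.e. the cohort the analysis was designed for.
* **Grid** — $\delta$ −0.5…10 ppm, 32768 points, mirroring a 32k-point
  acquisition; `peak_width` 0.0015 ppm. Tests and the acceptance script
  use 2048-point grids with `peak_width` widened proportionally
  (0.006 ppm) so lines stay resolved by several grid points; this keeps
  the full suite inside a few minutes without changing the physics being
  exercised.
* **`between_sample_cv` = 0.25, `reference_peak_cv` = 0.3** — free
  parameters: the study publishes no within-group variances. 25%
  biological CV is typical of tissue-extract metabolomics; 30% reference
  CV makes the reference peak clearly unusable for normalization, as
  observed in the study. These were chosen once and are not tuned.
* **`baseline_amplitude` = 0.2** — processed spectra are
  baseline-corrected, so the residual baseline must be a small fraction
  of total area (here a few percent). A large flat baseline would be
  unphysical and, because it does not scale with cell count, would leak a
  compositional artifact into total-area normalization.
* **`shift_jitter_sd` = 0.003 ppm** — about 2 Hz of drift, enough to
  degrade unaligned pairwise correlations noticeably and give RSPA real
  work.

What the generator does **not** emulate: FID-level effects (phasing,
apodization, window functions), lipid/macromolecule baselines, peak-shape
asymmetry, ridges, and metabolite-metabolite correlation beyond the
shared cell-count factor. Passing tests therefore demonstrate that the
*statistical machinery* behaves as specified on data satisfying its
assumptions — not that the pipeline is robust to every artifact of real
spectra.

## Preprocessing

**Order.** Region exclusion precedes normalization, so neither the water
band nor the TSP resonance contributes to the total area; alignment runs
before normalization on the excluded matrix. `run_pipeline()` fixes this
order.

**RSPA.** Each spectrum is aligned to the cohort's point-wise median
spectrum: the whole spectrum is shifted by the integer lag (bounded by
`max_shift_frac`, default 10% of segment length) that maximizes FFT
cross-correlation with the reference, then the segment is split at a
low-intensity point of the reference near the middle and the procedure
recurses (`min_segment` 128 points, `max_depth` 5). Ties between lags are
resolved toward the smallest magnitude, so an aligned segment stays put.
A sample's aligned spectrum is accepted only if its Pearson correlation
to the reference does not decrease — this makes the cohort-level
"alignment never hurts" guarantee structural rather than statistical. On
noisy but aligned data, sub-segments may still take one-point
adjustments; the guarantee is exact identity only in the noise-free
case. Segment parameters are not stated in the source study; the
defaults are standard RSPA practice and are all configurable.

**Cell-count normalization.** The study does not print a formula. The
convention implemented is: total-area normalization, rescaled per group
by average cell count relative to the reference group N, i.e. row
$x_i / (\mathrm{area}_i \cdot c_{g(i)} / c_N)$. Per-sample counts were
never published (only group averages with relative error), so a per-group
rescaling is the strongest statement the data support; it reproduces the
intended "approximate assessment of intracellular concentration changes"
and collapses to total-area normalization when all groups have equal
counts.

**UV scaling** drops zero-variance columns (their count is logged in an
attribute) and retains column means/SDs for exact inversion
(`uv_unscale()`) and for back-transforming loadings.

## Multivariate models

PCA is the SVD of the column-centred matrix with a deterministic sign
convention (largest-|loading| element positive). PLS-DA uses NIPALS with
a centred ±1 indicator for two classes (one-hot for more); per component
the X-weight is the normalized covariance direction, and X and Y are
deflated by the extracted score. VIP follows the standard definition, so
the mean of VIP² is exactly 1. Back-transformed loadings multiply each
variable's loading by its UV-scaling SD, recovering a pseudo-spectrum on
the intensity scale, paired with VIP for colouring.

**MCCV.** "7 blocks, 500 runs" is interpreted as repeated stratified
random hold-out of 1/7 of each class (at least one sample per class) per
run — Monte Carlo, not rotated K-fold; with classes of 6–9 samples a
rotated scheme would visit only a handful of distinct splits. Per run,
$Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$ on the held-out responses, with
TSS about the training-fold response mean; held-out predictions
(thresholded at the class-code midpoint) are pooled into one confusion
matrix, from which classification rate, sensitivity and specificity are
reported in percent (first class level = positive). Two further choices
matter:

* When handed an unscaled matrix, MCCV performs UV scaling *inside each
  training fold* and applies the training means/SDs to the held-out
  samples. Scaling the whole matrix first (as integrated chemometrics
  suites typically do) leaks held-out information into the model;
  with 5–9 samples per class the bias is material for honest $Q^2$.
* The number of components inside MCCV is a fixed argument (default 2)
  rather than a per-run model-selection loop: re-running the selection
  heuristic 500 times would dominate runtime and add a second layer of
  selection noise to the $Q^2$ distribution. At the model level,
  `choose_ncomp()` implements the usual heuristic (add components while
  cross-validated $Q^2$ improves by more than 0.01, capped at 5).

All Monte Carlo draws derive from one seed via pre-drawn per-run
sub-seeds, so results are reproducible and independent of evaluation
order. The class-stratified draw iterates classes in sorted label order,
which makes every MCCV statistic invariant to which class is coded
positive.

**STOCSY** is plain Pearson correlation/covariance of a driver variable
against the full matrix, on normalized (unscaled) spectra.

## Univariate screen

Windows (`assignment_table()`: one window per metabolite at its primary
multiplet, half-width 0.03 ppm) are integrated by the trapezoid rule on
the normalized spectra. For each window and group pair:

* **Routing** — Shapiro–Wilk in each group; both $p \ge 0.05$ routes to
  Welch's two-sided *t* (unequal variances: the groups are small and
  unequal), otherwise the two-sided Wilcoxon rank-sum test (exact where R
  computes it exactly, i.e. small samples without ties). Groups smaller
  than 3 route nonparametrically with a warning, as Shapiro–Wilk is
  undefined.
* **Effect size** — the study prints "ES ± error" without a formula.
  Hedges' *g* (small-sample-corrected standardized mean difference) with
  its standard error
  $\sqrt{(n_a+n_b)/(n_a n_b) + g^2/(2(n_a+n_b-2))}$ is adopted, and
  "error" is mapped to this SE: it reproduces the tables' |ES| > error
  inclusion rule. ES > 0 means higher in the first-named group.
* **FDR** — Benjamini–Hochberg across *all* integrated windows of one
  pairwise comparison, one family per normalization mode. The study's
  family cannot be recovered from the text (the printed p-values alone
  would all survive BH, yet the study reports five metabolites losing
  significance — the true family was evidently larger); the full window
  set is therefore a convention, stated here rather than a reproduction.

A window is *significant* when |ES| > SE and $p < 0.05$; the packaged
reference tables store exactly the rows passing this rule (one printed
row carries $p = 5.0\times10^{-2}$, so the fixture audit checks
$p \le 0.05$).

## Signatures

A `signature_pair` holds the same comparison under both normalizations.
The condition-specific signature intersects the *tissue* results of
several comparisons sharing a condition: members must be identified
(named, non-Ui) metabolites, significant in every contributing comparison
with the same direction relative to the condition. Direction consistency
is evaluated on sign only — the printed ES errors overlap too heavily for
magnitude comparisons to be meaningful. The FDR exclusion rule then
drops members that are FDR-nonsignificant in **every** contributing
comparison (default `"fdr_all"`). The alternative reading — drop on any
FDR failure — is selectable (`"fdr_any"`), but on the packaged tables it
contradicts the published 10-member pancreatitis signature (it would
also drop alanine and phenylacetate, which fail FDR only against LG),
whereas `"fdr_all"` reproduces it exactly, GPC being the single member
excluded. Cellularity classification is per metabolite within a pair:
significant in both views with the same sign $\to$ cell-independent;
tissue-only $\to$ cellularity-driven; anything else (cell-only or
conflicting signs) $\to$ ambiguous, with no special-casing of
borderline compounds.

## Numerical and degenerate-input choices

* ppm grids are stored descending (NMR convention); readers accept either
  orientation. Linear interpolation; out-of-range points are zeroed and
  counted.
* Lorentzian lines have exact unit analytic area; the area-conservation
  test compares the trapezoid integral against the closed-form truncated
  Lorentzian area, since tails outside the grid are genuinely absent.
* Integer-lag segment shifts pad with the boundary value.
* Zero total area, zero pooled SD with unequal means, zero-variance
  STOCSY drivers, and hold-outs that would empty a class are errors, not
  silent results; zero-variance columns at UV scaling are dropped and
  counted.
* Classification ties at the threshold go to the positive side of the
  midpoint; component signs are fixed by largest-|loading| positivity.

## Problem sizes used in validation

The test suite and the acceptance script run on 2048-point grids
(peak width 0.006 ppm), cohorts of 13–40 samples, 500-run MCCV (pooled
as 20 label permutations × 25 runs for the null calibration, so the
chance-level check averages over permutation-level as well as run-level
variation), a 420-sample null screen (42 two-group cohorts × 49 windows)
for the type-I error, and 1000-replicate effect-size consistency checks.
These sizes were chosen so the whole validation completes in minutes
while keeping every Monte Carlo margin several standard errors wide.

## Known limitations

* The multivariate headline numbers of the motivating study (e.g.
  $Q^2$ values near 0.97 for pancreatitis vs normal tissue) derive from
  the deposited experimental cohort; they are not reproducible from
  synthetic data and are not asserted anywhere. What is asserted is the
  machinery: calibration at chance on null data, near-perfect recovery on
  strongly separated data, and exact reproduction of the published
  table-derived counts and signature membership.
* Cell-count normalization uses group averages; per-sample cellularity
  is unavailable in principle.
* RSPA assumes segment-wise rigid drift; strongly crossing or swapping
  peaks are out of scope, as are icoshift-style alternatives and
  probabilistic quotient normalization.
* Multi-class MCCV confusion matrices are out of scope; models are
  pairwise, as in the motivating analysis.
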