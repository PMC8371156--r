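---
title: "Single-cell morphological profiling: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell morphological profiling: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmorph)
```

# The analysis in one paragraph

`cellmorph` implements a high-content-screening workflow for deciding
whether cultured cells from two groups of people — e.g. fibroblasts
from patients carrying a disease mutation versus healthy controls —
differ in morphology, and whether a drug moves the patient phenotype
back toward the control one. Each segmented cell is summarized by 124
features (31 per marker for four markers: DNA stain, mitochondrial
stain, acetylated α-tubulin stain, and the label-free phase-contrast
cell body). A binary logistic regression on the standardized features
assigns every cell a probability score in [0, 1] — its resemblance to
the group coded 1. Scores are averaged per individual, and all group
inference (t-tests, ANOVA/Tukey, ROC) happens on those per-individual
means: the person, not the cell, is the statistical unit, because cells
of one person are correlated through shared biology and batch.

# The feature engine

The 31-feature set per marker is:

| family | n | content |
|---|---|---|
| morph | 4 | area, length, width (principal-axis extents), roundness `4πA/P²` |
| intensity | 5 | mean, SD, min, max, sum |
| symmetry | 8 | `|Σ w e^{iYθ}| / Σw`, `Y = 2..5`, radial weight `w = I` or `I·e^{−r/r̄}` |
| compactness | 4 | brightest `q = 0.1..0.4` pixel fraction: `√(n_q/π) / (√2·R_g)` |
| axial | 2 | `4√λ₁` and `√(λ₂/λ₁)` from the mask pixel covariance |
| radial | 2 | intensity-weighted mean radius and its relative deviation |
| profile | 2 | intensity fraction deeper than half depth; mean normalized depth |
| texture | 4 | spot / hole / edge / valley filter-bank responses |

Conventions worth knowing:

* **Perimeter.** The roundness denominator uses the marching-squares
  contour of the mask after light anti-aliasing (Gaussian σ = 0.8 px).
  Contouring a raw binary grid overestimates a circle's perimeter by
  ≈ 7% (staircase bias), which would put a perfect disc at roundness
  0.87; with anti-aliasing a disc of radius 20 px scores 0.98. The cost
  is a small opposite bias for sharp-cornered shapes (a 41-px square
  scores 0.81 against the ideal π/4 ≈ 0.785).
* **Compactness ties.** "The brightest fraction q of pixels" is
  ill-defined on flat intensity; ties are broken toward the
  intensity-weighted centroid, which anchors the value at exactly 1 for
  a uniform solid disc — the feature's dimensionless reference point.
* **Texture filters.** Spot/hole/valley are built from the eigenvalues
  `h₁ ≤ h₂` of the Hessian of the σ-smoothed image (default σ = 1 px,
  single scale): `spot = mean √(h₁h₂)` where both eigenvalues are
  negative, `hole` the same where both are positive, `valley =
  mean max(0, −h₁ − 3|h₂|)`, `edge` the mean gradient magnitude, each
  normalized by region mean intensity. The sign gating matters: a naive
  "negative smaller eigenvalue" valley responds over the entire tail of
  an isotropic blob (every radially decaying profile has negative
  tangential curvature), and would score a spot image *higher* than the
  spot filter itself. The gated forms give clean discrimination —
  blobs drive spot, filaments drive valley. The region is eroded by
  `⌈2σ⌉` px before averaging so the mask boundary (a huge intensity
  step) does not dominate; if erosion empties a small mask the full
  mask is used and a message emitted.
* The symmetry radial-decay weight is `e^{−r/r̄}` with `r̄` the
  intensity-weighted mean radius: parameter-free and scale-adaptive.
* All intensity-weighted features are pure pixel sums and are tested
  against independent brute-force summation at 1e−9 relative
  tolerance; morphology and symmetry are checked for translation and
  90° rotation invariance, and intensity features for linear gain
  response.

# Segmentation

Nuclei: Otsu threshold of the Gaussian-smoothed (σ = 2 px) nucleus
channel, watershed on the distance transform to split touching nuclei,
minimum-area filter. Cytoplasm: seeded propagation of nucleus labels
over the thresholded whole-cell channel (EBImage's Voronoi-style
`propagate`), so each cell region inherits its nucleus label and
contains it. These are functional equivalents of the closed-source
"find nuclei / find cytoplasm" stages of commercial HCS software, not
replicas; the renderer's ground-truth masks put a floor under them
(planted cell counts recovered exactly for non-touching fields,
per-cell Jaccard ≥ 0.9).

# The synthetic cohort generator

Real patient images are not available, so the generator is the study's
data source and defines its conditions. At the feature-table level,
cell `c` of individual `i` in group `g` has

```
x = baseline + g·δ·(1 − reversion·treated) + b_i + ε
```

with `δ = effect_size·√(1 + individual_sd²)` on the affected features
(so `effect_size` is the shift in pooled cell-level SD units),
`b_i ~ N(0, individual_sd)` per feature shared by all of an
individual's cells, and `ε` unit-variance noise equicorrelated
(default ρ = 0.3) within each (marker, family) block — logistic
regression must cope with collinear inputs, as real morphology features
are strongly correlated. Affected features are spread round-robin
across the four markers so every marker subset carries signal.
Treatment reverts the planted shift on configurable markers only,
emulating a drug that rescues some organelle phenotypes and not others.
Defaults mirror the case/control design of the motivating cohorts
(9 + 10 individuals, hundreds of cells each, individual_sd 0.3).

What the generator does *not* emulate: non-Gaussian feature marginals,
cell-cycle substructure, plate-position effects, segmentation errors
correlated with phenotype. Passing tests therefore show that the
statistical machinery is correct under its stated model, not that the
pipeline's effect sizes transfer to real fibroblasts.

The image renderer exercises the segmentation/extraction path
end-to-end: five aligned channels (elliptical nuclei, star-shaped cell
bodies with protrusions, elongated mitochondrial blobs, radial tubulin
filament strokes, textured phase-contrast body) with Poisson shot noise
and Gaussian read noise, plus ground-truth label masks. It makes no
attempt at optics (no PSF, no z-structure).

# Scoring, leakage, and why two modes exist

`fit_cell_classifier()` fits unpenalized maximum-likelihood logistic
regression on features standardized with training-set constants (stored
in the model — essential for transfer scoring). Under quasi-separation
the fit is retried with a tiny ridge (1e−6) on the slopes; the
intercept stays unpenalized, so the in-sample identity
`Σ p̂ = n₁` survives the fallback exactly.

The default workflow scores the training cells themselves
(**in-sample**), matching the published procedure of fitting on all
cells and reading scores off the same cells. This mode leaks: with
per-individual random effects, the fit memorizes individual signatures,
and even without them the in-sample fitted group gap is shared by all
individuals of a group. The measurable consequence is that a cohort
with *no* group effect still yields individual-level AUC ≈ 1 in-sample.
`score_cells_cv()` is the honest alternative — folds are grouped by
individual (stratified by group), each person is scored by a model
that never saw their cells — and is the mode under which the null
calibration holds: over 200 replicate null cohorts the mean
individual-level AUC is 0.5 (chance) within Monte-Carlo error. Both
modes are exposed; which one a claim uses is stated wherever numbers
are reported.

Probability scores of the paper-matching in-sample mode are what the
fold-difference readout (`fold_difference()`: mean case probability /
mean control probability) and score histograms are computed from.

# Normalization and reproducibility

Features are z-scored to negative-control (healthy-control) cells per
run and per feature: `x' = (x − μ_ctrl,run)/σ_ctrl,run`. This removes
any per-run affine batch effect by construction, is idempotent, and
near-zero-variance features (σ < 1e−12) are centered but passed through
unscaled — flagged, never dropped, preserving the 124-column contract.
The run-reproducibility check pools two runs of the same individuals,
uses run membership as the outcome of a logistic regression, and
declares the runs reproducible when no individual's mean run-A/run-B
probabilities differ by more than a margin (default 0.05). The check
scores out-of-fold (cells split within each individual × run stratum):
scored in-sample, the fit memorizes run-specific noise and a genuinely
reproducible pair of runs fails the margin.

# Transfer scoring and the rescue call

A frozen case-vs-control model (trained on untreated cells only — a
leakage guard refuses anything else) scores the drug-treated patient
cells with its stored standardization; nothing is refit. Per-individual
treated means then enter a one-way ANOVA with untreated control and
patient means, with Tukey HSD for the three contrasts, and the call is:

* **rescued** — treated differ from untreated patients (p < α) and not
  from controls (p ≥ α);
* **partial** — treated differ from neither, but their mean lies
  strictly between the patient and control means;
* **not rescued** — otherwise.

α defaults to 0.05 and both Tukey p-values are always reported, because
the call is threshold-sensitive near the boundary.

One property of this design deserves emphasis. The treated cells come
from the *same individuals* as the untreated patient training cells.
With few individuals per group, the difference between the groups'
average random effects is itself a legitimate in-sample discriminant —
and that component does not revert under treatment. It elevates treated
scores above controls by an amount scaling like `individual_sd²`, while
the between-individual spread (which the Tukey test uses as its
yardstick) scales like `individual_sd`. At `individual_sd = 0.3` with 5
individuals per group, a fully reverted phenotype is still called
"different from controls" in a large fraction of replicates — not an
implementation defect but a power pathology of transferring a
same-individual in-sample classifier. The rescue-recovery property test
therefore runs at conditions where the design is well-posed (8 + 8
individuals, 200 cells each, effect 1.5 SD, `individual_sd = 0.05`,
full reversion on the tubulin and mitochondria markers), where the
planted per-marker design is recovered in ≥ 95% of replicates.

# Numerical and procedural choices

* ROC is computed over individuals; the AUC uses the Mann–Whitney
  midrank identity (ties count ½) and equals the trapezoidal area under
  the threshold-sweep curve to 1e−12.
* Student's t-test (equal variances) is the default two-group test,
  Welch by flag; degenerate zero-variance inputs return `t = 0, p = 1`
  (identical groups) or an underflow-safe minimal p.
* No multiple-testing correction across marker sets by default; raw
  p-values are reported.
* Coordinates are 0-based (row, col); masks are 4-connected; label
  masks use positive consecutive integers.
* All generators are pure functions of (config, seed); the session RNG
  is saved and restored.
* Problem sizes in the test-suite and in `scripts/acceptance.R` (e.g.
  500 cells/individual for the strong-effect cohort, 200 replicates of
  15 + 15 × 200 cells for the null calibration, 3-fold grouped CV) were
  chosen so the full analysis re-runs in minutes on one CPU while
  keeping Monte-Carlo error well inside the asserted tolerances.

# Known limitations

* The 31-feature set matches the published feature *families* and
  count, but the commercial feature definitions are proprietary; exact
  numerical replication of those values is out of scope.
* Texture is single-scale (σ = 1 px) by default.
* The image renderer is a test harness, not a microscopy simulator.
* AUC confidence intervals (e.g. DeLong) are not provided.
* The profile family's two-feature definition (depth-weighted intensity
  location) is a stand-in for an under-specified original.
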