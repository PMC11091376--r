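---
title: "Personalized head FE models: methods and design notes"
author: "headmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized head FE models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headmorph)
```

# The problem

Head injury risk for vulnerable road users (pedestrians and cyclists) in
vehicle collisions depends not only on impact conditions but on the
geometry of the individual head. Studying that dependence at population
scale requires many *personalized* head finite-element (FE) models — more
than can be built by hand from CT data — plus a way to turn simulated
brain-tissue responses into injury severity labels, and an evaluation
protocol for models that predict severity from easily measured subject
characteristics.

`headmorph` implements that pipeline as reusable pieces: a landmark
statistical shape model driven by anthropometric characteristics,
thin-plate-spline (TPS) morphing of a baseline skull+brain mesh, mesh and
geometry validation, a CORA-style signal biofidelity rating, a five-degree
von Mises injury classifier, and a cross-validated prediction harness. A
set of synthetic generators supplies every input the pipeline needs, with
known ground truth, so everything is testable without clinical data.

# Landmark shape model

Each subject is represented by $m$ ordered skull landmarks (default
$m = 69$), stacked into a $3m$-vector. Across $n$ subjects (default
$n = 124$) the model is

$$x_i \approx \bar{x} + U \, p_i, \qquad p_i \approx A \, z_i + \varepsilon_i,$$

where $U$ is the $3m \times k$ orthonormal PCA basis (default $k = 40$),
$p_i$ the component scores, $z_i$ the centred characteristic vector
(gender 0/1, age in years, stature in m, BMI in kg/m²), $A$ the $k \times 4$
regression coefficient matrix and $\varepsilon_i$ the per-subject residual.
The score regression is intercept-free; PC scores are mean-centred by
construction, so the characteristics are centred (optionally unit-scaled)
before the per-component least-squares solve to make that form well-posed.

Configurations can first be rigidly superimposed (generalized Procrustes,
rotation and translation only). Scaling is deliberately **not** removed:
stature and BMI drive head size, so size is signal for the regression.
Whether the source CT frames warrant alignment is data-dependent; the
synthetic generator emits configurations in a common frame, and the exact
coefficient-recovery checks therefore run with alignment off.

New landmark sets are predicted by evaluating the fitted chain at given
characteristics. To homogenize the characteristic distribution before
batch prediction, `sample_design_grid()` builds a full-factorial grid;
the default layout is 2 genders × 5 ages (10–90 yr) × 5 statures
(1.45–1.95 m) × 4 BMI levels (15–35), i.e. 200 design points. Only the
total of 200 is fixed by the study design being emulated; the 2×5×5×4
split and the axis ranges are this package's convention, chosen to cover
the synthetic cohort's sampler ranges evenly.

# Thin-plate-spline morphing

Baseline-to-subject morphing solves the volumetric TPS / biharmonic
radial-basis interpolant

$$f(x) = c + Bx + \sum_{i=1}^m w_i\, \varphi(\lVert x - s_i \rVert),
\qquad \varphi(r) = r,$$

with side conditions $\sum_i w_i = 0$ and $\sum_i w_i s_i^\top = 0$, which
make the transform reproduce affine maps exactly. $\varphi(r) = r$ is the
standard 3-D volumetric choice. One global field drives *all* nodes —
skull shells and brain solids alike — so interior tissue follows the skull
geometry; there is no sliding or contact handling.

Numerical notes:

* The $(m+4)$-square symmetric system is solved densely; at $m \approx 69$
  this is trivial. The system is assembled in a centred, unit-RMS-scaled
  source frame and mapped back exactly (legitimate because the kernel is
  homogeneous); this keeps the condition number around $10^2$ instead of
  $10^6$ at head scale, and landmark interpolation residuals at the
  $10^{-13}$ mm level.
* Kernel evaluation uses coordinate differences directly rather than the
  expanded $\lvert x\rvert^2 + \lvert s\rvert^2 - 2 x\cdot s$ form, which
  loses half the significant digits exactly at the landmarks.
* `lambda = 0` (exact interpolation) is the default, matching the
  landmark-matching intent of the morphing step; `lambda > 0` gives a
  smoothed fit and the landmark residual is non-decreasing in `lambda`.
  Duplicate or coplanar sources raise singular-system errors naming the
  offending rows; condition numbers above $10^{12}$ warn.

# Mesh and geometry validation

The quality instruments mirror standard FE practice; the two named
indicators are deliberately interpreted as the most common definitions,
and both are pluggable if a different convention is needed:

* **Scaled Jacobian** — per corner, the determinant of the corner's edge
  triad normalized by the edge lengths (solids), or the normalized corner
  cross product signed by the element normal (shells); the element value
  is the corner minimum. 1 is ideal; values ≤ 0 indicate degenerate or
  inverted corners. Zero-length edges yield −1 with a `degenerate` flag
  instead of an exception.
* **Equiangular skew** — the worst relative deviation of interior face
  angles from the ideal (90° quad faces, 60° triangular faces); solids
  take the worst face. 0 is ideal, 1 degenerate.

Both metrics are invariant under rigid motion and uniform scaling, which
provides the validation oracles: such morphs must produce exactly zero
change rates. The per-element change rate against the baseline is
$\lvert q_\text{morph} - q_\text{base}\rvert / \max(\lvert q_\text{base}\rvert, 10^{-3})$;
the floor avoids blow-up on near-degenerate baseline elements.

Geometric accuracy is the exact point-to-triangle distance from each
skull-surface node to the target surface (a centroid-radius lower bound
prunes the scan without changing the result). The default acceptance
gates are: mean geometric error < 4 mm, max < 5 mm, mean quality change
< 5 %, max change < 10 %, minimum scaled Jacobian > 0.2 — the thresholds
used to accept personalized head models in the study this package
emulates. All gates are configurable and relaxing one can never flip a
pass into a fail.

# Biofidelity rating (CORA-style)

Signal agreement is scored in $[0,1]$ by combining a corridor rating with
cross-correlation sub-ratings. The exact CORA release and settings behind
published score tables are generally not reported, so this module fixes a
fully specified variant:

* corridors of constant half-width, `a0·max|ref|` (inner, default 0.05)
  and `b0·max|ref|` (outer, default 0.5); per-sample score 1 inside the
  inner corridor, 0 outside the outer, linear between; averaged over the
  window;
* cross-correlation block on a 1000-point common grid: the integer-sample
  shift within ±`d_max`·T (default `d_max` 0.12) maximizing the Pearson
  correlation (ties toward the smallest shift) gives shape = max(0, ρ),
  size = min/max ratio of squared-signal integrals over the shifted
  overlap, and phase = 1 − |shift|/(`d_max`·T);
* total = 0.5·corridor + 0.5·(0.5·shape + 0.25·size + 0.25·phase).

Self-rating is exactly 1; a ×2 amplitude copy scores size 1/4; a delay of
half the allowed window scores phase 0.5. Reference cadaver signals are
not distributable, so published score values are not reproduced here —
the module is validated against these analytic constructions instead.

# Injury classification and dataset

Peak brain-tissue von Mises stress (kPa) maps to five injury degrees:
J1 minor (< 6), J2 cerebral contusion [6, 11), J3 moderate [11, 15),
J4 cerebral concussion [15, 27), J5 severe (≥ 27). Printed band notation
of the form "6–11" is ambiguous at the boundaries; this package fixes the
half-open, left-closed convention, so a value exactly at 6 kPa is J2.

`dataset_summary()` reproduces the descriptive views used to read such
datasets: per-speed mean and central 90 % interval, class-share
distributions by height band, gender, age decade and BMI band, and the
pedestrian-vs-cyclist comparison.

# Synthetic study conditions

The generators' defaults *are* the emulated study conditions, fixed once:

* **Landmark population** — n = 124, m = 69; gender Bernoulli(0.5), age
  U(10, 90) yr, stature N(1.61/1.73, 0.09) m by gender (height is the only
  characteristic correlated with gender), BMI U(15, 35). Geometry is a
  head-sized ellipsoidal template plus a rank-5 linear characteristic
  effect (leading mode: radial size, loaded on stature and BMI) plus
  isotropic landmark noise (default sd 0.5 mm). With zero noise the
  population is exactly linear, which makes coefficient recovery an exact
  oracle.
* **Baseline mesh** — quadrilateral skull shells on the ellipsoid
  (latitude bands kept away from the poles so the coarse default passes
  the Jacobian gate) and a perfect hexahedral brain lattice inscribed
  inside; 69 landmark nodes spread over the shell; a companion triangle
  surface shares the shell vertices.
* **Injury dataset** — 1812 records: 9 speed levels (20–60 km/h, 5 km/h
  grid) × 2 states, with 12 cells of 101 records and 6 of 100. The
  emulated study reports only the total of 1812; this near-factorial
  layout is the package's documented convention. Within each cell, age
  and BMI take evenly spaced grid values with random pairing and gender
  alternates, so characteristic margins are balanced across speed and
  state — this balance is what keeps the calibrated band contrasts stable
  across seeds. The latent response is
  `speed + 0.062·(age−10) − 0.235·(bmi−25) − |height−1.70| +
  1·pedestrian + N(0, 0.25)` (latent units; speed term in km/h above 20),
  min–max rescaled so the realized dataset spans exactly 4.4–46.9 kPa —
  calibration by construction. The effect sizes were calibrated once so
  the severe-injury (J5) prevalence gap is ≈10 percentage points between
  the age > 80 and age 10–20 bands and ≈8 points between the BMI 15–20
  and 30–35 bands (across-seed sd ≈ 1.1 and 0.8 points). The stature
  effect is deliberately non-monotone (piecewise around 1.70 m) to mirror
  the erratic height finding.
* **Signal pairs** — half-sine pulses (identical / scaled / noisy kinds)
  and a periodic sine with a constructed delay (shifted kind), each with
  an analytic expected rating.

What the generators do **not** emulate: real skull geometry (the template
is an ellipsoid), nonlinear characteristic effects on shape, crash
mechanics (the injury response is a calibrated statistical surrogate, not
a physical simulation), and measurement artefacts of CT landmarking.
Passing tests therefore demonstrate the correctness of the algorithms and
the faithfulness of the pipeline's contracts, not clinical validity on
real cohorts.

# Prediction harness

The evaluation protocol standardizes features (statistics fitted on the
training rows of each fold only — the protocol source says only that data
were standardized; fitting per training fold is this package's choice, to
preclude leakage), shuffles records into 10 near-equal folds, and reports
per-fold and mean metrics. Classification metrics are accuracy, recall,
F-score and one-vs-rest AUC; the multi-class averaging scheme is not
stated by the emulated protocol, so recall/F/AUC are **macro**-averaged
over classes present in the truth. Regression metrics are R², MSE and
MAE; for a zero-variance truth, R² is reported as 1 only when predictions
are exact and flagged undefined otherwise.

Grid search evaluates a finite hyperparameter grid exhaustively, selecting
maximum mean accuracy (classification) or minimum mean MSE (regression),
with ties broken by first-in-grid order. Two reference estimators are
built in — a k-nearest-neighbour classifier and a closed-form ridge
regressor — so the harness is fully testable without external learning
libraries; the published study's eight ML/DL architectures attach through
the same estimator contract and are intentionally not re-implemented
(their printed scores depend on data that cannot ship).

# Problem sizes and determinism

The bundled tests and the acceptance script run the pipeline at its
native scale: 124 × 69 landmark fits with k = 40, 1812-record injury
datasets, meshes of a few hundred elements, and 1000-point signal grids;
the whole suite completes in a few seconds. Every stochastic step takes
an explicit seed, and each generator seeds its own stream, so any single
artifact is reproducible in isolation.

# Known limitations

* The keyword mesh format covers nodes, shell/solid elements and node
  sets only — no materials, contacts or controls.
* Procrustes alignment is rotation+translation only by design; reflection
  is never applied.
* The corridor rating uses constant-width corridors from the reference
  peak, not local corridors from an experimental ensemble.
* The TPS field is global; extreme target configurations can invert
  elements, which the quality gates will catch but the morph itself will
  not prevent.
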