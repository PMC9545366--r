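---
title: "Statistical shape modeling of the proximal femur and hip OA outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape modeling of the proximal femur and hip OA outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipshapes)
library(dplyr)
```

## The model

`hipshapes` implements a two-dimensional statistical shape model (SSM) of the
left proximal femur and superior acetabulum, annotated by 85 ordered landmark
points (mm, AP view, x medial-positive, y superior-positive). The pipeline
has five statistical stages:

1. **Generalized Procrustes analysis (GPA).** All configurations are centred,
   scaled to common centroid size (scale removal is on by default, the
   classical point-distribution-model choice, and configurable), and
   iteratively rotated onto the evolving mean until the mean changes by less
   than `1e-10`. In 2-D the optimal rotation has a closed form,
   `theta = atan2(sum(x*my - y*mx), sum(x*mx + y*my))`, so alignment is fully
   vectorised.
2. **Principal component analysis.** The aligned coordinate matrix (n
   subjects by 170 coordinates) is decomposed into orthonormal modes of
   variation — hip shape modes (HSMs) — ordered by explained variance. Scores
   are standardized to mean 0, SD 1 over the training set; the
   unstandardized per-mode SDs are kept for composite reconstruction. PCA
   signs are arbitrary, so each mode's largest-magnitude loading is made
   positive, pinning refits to identical models.
3. **Geometric morphometrics.** From each configuration in original mm
   coordinates: the least-squares femoral head circle (Kasa algebraic fit
   with geometric refinement, points 15–28); the alpha angle (AA); the
   lateral centre-edge angle (LCEA, lateral edge = point 78); the neck-shaft
   angle (NSA); the narrowest neck width (NNW); and the minimum joint-space
   width (mJSW, superior head points 22–31 against acetabular points 78–84).
   Widths are polyline-to-polyline minima (point-to-segment, both
   directions), because landmarks sample a continuous contour.
4. **Radiographic OA grading.** Osteophyte areas at three sites are graded
   0–3 by configurable thresholds, height-adjusted mJSW is graded 0–3, and
   the summed 0–12 score maps to an overall radiographic hip OA (rHOA)
   grade with two binary outcomes: moderate disease (grade 2 only) and
   grade ≥ 3.
5. **Association models.** One logistic (or Cox, for time to total hip
   replacement) model per mode: the standardized score as single exposure,
   adjusted for age, sex, height, weight and binary white/other ethnicity,
   optionally further adjusted for AA or LCEA. Effects are ORs/HRs per 1 SD
   with Wald 95% CIs; multiplicity is controlled at a strict Bonferroni
   threshold `0.05 / k` (0.005 for the conventional 10 modes). Modes passing
   the threshold are combined into a composite outline:
   `mean + sum(beta_i * sd_i * factor * mode_i)` with a visual factor of 5
   that is stored in the output so exaggerated displacements are never
   mistaken for millimetres.

## Geometric conventions and numerical choices

* **Alpha angle.** A circle is fitted to the head points; the outline is
  walked from the superior head along the superior neck border, and the
  junction is where the contour first leaves a departure circle of radius
  `r * (1 + delta)`. Two choices matter and are deliberate:
  * the junction is the *interpolated crossing* on the first outline segment
    passing from inside to outside the tolerance (a landmark set samples a
    continuous contour, and a vertex-quantized junction would move in jumps
    of the landmark spacing, ~16 degrees here);
  * `delta = max(0.02, 3 * rms / r)` by default, with the additional
    requirement that the following vertex is also outside. A narrower,
    2-sigma-style band would let ordinary landmark noise trigger spurious
    junctions in a sizeable minority of subjects; tying the band to three
    times the circle-fit residual keeps the detector quiet under noise while
    still responding to genuine cam-type departure. `delta` is an explicit
    argument, so other conventions can be swapped in.
* **Neck axis.** "Centre of the neck" is not otherwise defined; the axis
  runs from the fitted head centre through the midpoint of the minimising
  segment of the narrowest-neck computation.
* **LCEA sign and frame.** LCEA is measured against the vertical through the
  head centre — perpendicular to the *image* x-axis. It is therefore
  translation- and scale-invariant but intentionally not rotation-invariant;
  all other measures are fully rigid-motion invariant. Negative LCEA (true
  dysplasia) is reported, not clipped.
* **NSA** is the obtuse angle between the neck axis and the
  total-least-squares line through paired medial/lateral shaft midpoints
  (total least squares because the shaft is near-vertical and ordinary
  regression would degenerate).
* **Circle fit** refuses collinear points; `mJSW` returns 0 with a warning
  when the two polylines intersect (bone-on-bone contact).
* **mm measures are always computed in original coordinates**, never the
  Procrustes frame, since alignment removes size.

## The synthetic cohort generator

No individual-level hip imaging data are openly deposited, so the package
ships a first-class generator that emulates the data structure the analysis
assumes. It is built from:

* a **parametric template** (head circle r = 25 mm, neck width 31.6 mm, NSA
  135 degrees, joint gap 4 mm, LCEA 35 degrees) whose construction
  guarantees the printed index conventions (head-circle points exactly on
  the circle, parallel neck-border stretches exactly the neck width apart);
* six **orthonormal deformation fields** — head size, neck width, cam-type
  junction bump, acetabular coverage rotation, trochanter size, neck length
  — hand-designed, projected off the similarity-transform tangent space
  (translation, rotation, scaling; alignment removes exactly those
  components, so only similarity-free fields are recoverable), then
  Gram–Schmidt orthonormalized. Scores are independent Gaussians; the
  default SDs (4, 3, 3, 5, 2.5, 2 mm) were chosen once to give realistic
  dispersions of the geometric measures (AA SD ~10 degrees, LCEA SD ~3
  degrees, NNW SD ~1.2 mm at the default template);
* **isotropic Gaussian landmark noise** (default 0.5 mm), of the order of
  manual point-correction distances on DXA annotations;
* **covariate margins** from a large population imaging cohort (age
  N(63.7, 7.6) years, 47.8% male, sex-specific heights and weights, 96.8%
  white ethnicity) — documented defaults, not fitting targets;
* **outcome models**: logistic for the three prevalent outcomes and an
  exponential proportional-hazards model with a 6-year administrative
  censoring horizon for hip replacement. Intercepts are calibrated by
  Monte-Carlo (private fixed RNG stream, `uniroot`) so default marginal
  prevalences are approximately 5.7%, 1.7%, 1.3% and 0.6%;
* **osteophyte areas** drawn from zero-inflated gamma distributions
  conditional on case status, so the grading stage sees realistically
  skewed inputs.

### Realized morphology drives risk

A design point worth spelling out: for the two named morphologies the
outcome models act on *realized geometric feature scores*, not the latent
mode scores. The cam term uses the subject's realized junction-departure
angle (computed from the rendered, noise-inclusive landmarks against the
true head circle with the same crossing rule as the measured AA); the
coverage term uses the realized angle of the lateral acetabular edge. Both
are standardized against a fixed reference distribution drawn at
specification time. All other modes act per SD of latent score.

The reason is identifiability of the adjustment analyses. If outcomes
depended on the latent score, the fitted mode score would be a nearly
perfect exposure measurement, the true effect of adding AA or LCEA to the
model would be essentially zero, and the observed "attenuation" would be
an artifact of shared landmark-measurement noise with seed-dependent sign.
With risk following the realized morphology — which is also the
epidemiologically sensible reading: joints impinge because of their actual
junction shape, not because of a cohort-level summary coordinate — the
measured AA and LCEA are direct estimates of the risk-relevant quantity, a
global mode score is a coarse summary of it, and angle adjustment removes a
genuine, directionally stable share of the mode–outcome association. This
is exactly the contrast the association stage is designed to expose.

### What the generator does not emulate

Real DXA outlines have correlated, anisotropic annotation error, osteophytes
that deform the outline locally, left/right asymmetry, and shape–covariate
dependence (e.g. sex differences in NSA and NNW); the generator has none of
these. Passing tests therefore demonstrate that the pipeline's statistics
are correct under its stated assumptions, not that the effect sizes
transfer to any real cohort.

## Grading constants

The osteophyte area thresholds (1, 4, 9 mm² per site), the JSN cut-points on
height-adjusted mJSW (2.5, 2.0, 1.5 mm) and the total-score-to-overall-grade
map (0 → 0, 1–2 → 1, 3–4 → 2, ≥ 5 → 3) are documented placeholders: the
published grading defers the numeric cut-points to an atlas-based protocol
that does not print them. They are pinned by the test suite and fully
configurable through `grading_config()`. A value exactly at a cut-point
takes the lower grade, on both the area and the narrowing side.

Height adjustment of mJSW is the residual from a least-squares regression of
mJSW on height plus the cohort mean — a declared choice (the exact published
adjustment is unstated); it leaves adjusted values height-decorrelated,
shift-invariant in height, and on the original mm scale.

## Attenuation readouts

Attenuation of an OR under additional adjustment is reported on the
excess-odds scale, `100 * (OR_base - OR_adj) / (OR_base - 1)`. Applied to a
published worked example (1.49 falling to 1.19 under AA adjustment) this
gives 61.2%, consistent with the printed "more than 60%" bound, whereas a
log-scale version gives 56% and fails it — which is why the excess-odds
scale is the package default. The same formula handles protective ratios
through the shared excess term; a base ratio of exactly 1 is undefined and
returns `NA`.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds; `sample_cohort()` and
`run_hip_pipeline()` are byte-deterministic given a seed. The package's own
validation uses cohorts of 10,000–20,000 subjects for recovery and
adjustment properties (a size at which Monte-Carlo error is well below the
tested margins), 200 replicates at n = 20,000 for CI-coverage checks, and
n = 50,000 for prevalence calibration checks; the worked-example pipeline in
the README runs at n = 2,000 in a few seconds.

```{r example, eval = FALSE}
sim <- sample_cohort(n = 2000, seed = 1)
model <- fit_shape_model(sim$landmarks)
glance(model)
measures <- measure_hips(sim$landmarks)
results <- fit_hsm_logistic(model$scores, sim$cohort, "rhoa_ge3") |>
  bonferroni_flag()
composite <- build_composite(model, results, "rhoa_ge3", factor = 5)
ggplot2::autoplot(composite)
```

## Known limitations

* 2-D AP-view geometry only: no Dunn-view or 3-D alpha angle, no right hips.
* The composite shape is a visualisation, not an inferential object; no
  uncertainty is propagated to the outline.
* Sex-stratified composites reuse the sex-combined shape model with
  stratified coefficients; a fully stratified variant would refit the SSM.
* The generator's six modes cannot represent localized osteophytes, so
  grading inputs (areas) are simulated directly rather than measured from
  the outline.
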