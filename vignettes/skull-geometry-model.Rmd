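---
title: "Statistical shape modelling of the growing pediatric skull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape modelling of the growing pediatric skull}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skullgeom)
```

## The problem

The skull of a child under three changes rapidly in size and in structure:
cranial sutures and fontanels -- fibrous gaps between the bony plates --
ossify on a location-dependent schedule, and the bone itself thickens
non-uniformly, more in the occipital region than frontally or parietally.
Head-injury assessment tools (finite-element head models, child crash-test
dummies) need a *parametric* description of this geometry: given an age and
a head size, produce a realistic skull with the right shape, suture widths
and thickness distribution.

`skullgeom` implements such a statistical skull geometry model as a tested,
reusable pipeline.  Real CT-derived landmark data of this kind are not
publicly available, so the package also contains a first-class synthetic
cohort generator that emulates the statistical structure the analysis
assumes, and every stage is validated against that generator's ground truth.

## The landmark representation

Assuming left-right symmetry, one half of the skull is described by 92
landmarks in the newborn layout:

* 64 **suture-boundary** landmarks: 32 pairs flanking the suture lines, one
  pair per suture location (`S01A`/`S01B`, ...);
* 24 **surface** landmarks `B01`--`B24`, placed by relative-position rules
  (e.g. `B12` midway between `S27` and `S14`, `B14` midway between `B12`
  and `S14`);
* 4 **convergence** landmarks `C01`--`C04` at suture intersections.

Reprocessing (`pair_to_midline()`) replaces each open pair by its midpoint
-- the suture *centerline* landmark `S01`...`S32` -- plus the Euclidean
distance between the pair members as the **suture width**.  A closed suture
is digitized as the centerline landmark directly and gets width 0, and any
width below 0.5 mm is set to 0 (narrower gaps cannot be meshed in the
downstream finite-element use of the model).  The comparison uses a 1e-9 mm
numeric guard so a separation of exactly 0.5 mm survives floating-point
distance recomputation.  The homologous representation is therefore 60
landmarks, 32 widths and 25 thickness values per subject; thickness is
recorded at the 24 surface landmarks plus `C04` (the source layout records
25 thickness values but names only the 24 surface labels; attaching the
25th to a low posterolateral convergence is this package's choice).

Rigid registration (`align_geometry()`) puts every subject in one
anatomical frame: `S01` (the inferior end of the midline suture chain, near
the frontal bone) at the origin; the total-least-squares plane through all
midline-flagged landmarks as the mid-sagittal `y = 0` plane (all midline
landmarks are used -- the fitting subset is not prescribed by the source);
the `x` axis along `S01`-to-`C01`, so `C01` lands on the positive `x` axis;
and the handedness fixed by requiring the landmark centroid at positive
`z`.  `C01` must therefore be a *midline* convergence (the anterior
fontanel region); the identities of `C01`--`C04` are otherwise opaque
labels.  Because the frame is defined purely by landmarks, alignment is
idempotent and recovers any known rigid motion exactly; being rigid, it
preserves all inter-landmark distances.  There is deliberately **no**
Procrustes scaling: size is signal in a growth model.

## Features: age and CirOffset

Head circumference is measured as the perimeter of a closed 3D polygon
through a fixed loop of landmarks near the maximal axial contour, mirrored
across the mid-sagittal plane (`measure_circumference()`).  An inscribed
polygon underestimates a smooth contour slightly, but the same loop is used
for every subject and by the generator's calibration, so the measure is
homologous; skull landmarks, not skin, define it.

Circumference is strongly correlated with age, which would destabilize a
regression using both.  The model therefore uses **CirOffset**: the
subject's circumference minus the reference median circumference at the
subject's age.  The bundled reference curve is the saturating growth law

$$c(a) = 35\,\bigl(1 + 0.411\,(1 - e^{-a/8.2})\bigr)\ \text{cm},$$

rising from 35 cm at birth to about 49.2 cm at 36 months with a decelerating
derivative -- the shape and endpoints of a population median chart.  It is
a parametric fixture bundled with the package (no external growth-chart
data are shipped); the generator and the feature computation share it, so
offsets are self-consistent.

## The statistical geometry model

Per subject, three vectors are formed: 60 landmarks times 3 coordinates
(length 180), 25 thickness values, 32 suture widths.  Stacked over an
n-subject cohort these give n x 180, n x 25 and n x 32 matrices
(`assemble_matrices()`).  The model (`fit_skull_model()`) is, per block:

1. **PCA** (mean-centered SVD), retaining the smallest number of components
   whose cumulative variance reaches 95%.  Component signs follow a
   deterministic convention (largest-magnitude loading positive), and the
   retained count is capped at `n - p - 1` so step 2 stays overdetermined.
2. **Principal-component regression**: ordinary least squares of the PC
   scores on the feature design `[1, age, CirOffset]`.  The intercept is
   mathematically required even though the conceptual features are age and
   CirOffset alone -- without it the regression could not reproduce the
   mean geometry.  The three blocks are fitted independently with a shared
   design; nothing couples their residuals.

Prediction evaluates `C f`, reconstructs each block, clamps negative
predicted widths to 0 (a linear model happily extrapolates a closing suture
below zero) and floors thickness at 0.1 mm so downstream meshing always
sees positive bone.  Before clamping, prediction is exactly affine in the
features.  Ages outside the fitted range warn rather than error.
Validation (`validate_model()`) predicts held-out subjects from their age
and measured offset and reports per-axis signed errors (predicted minus
observed), pooled over landmarks and subjects.

Models serialize to versioned JSON with doubles written as `%.17g` decimal
strings, so a save/load round trip reproduces every prediction bit for bit.

## The synthetic cohort generator

The generator (`cohort_spec()`, `sample_cohort()`) replaces the
unavailable CT cohort and defines the study conditions:

* **Cohort**: 56 subjects by default; ages uniform on 0--36 months;
  circumference offsets Normal(0, 1.2 cm).  Under these conditions the
  empirical age-circumference correlation is about 0.83 (high, as in
  comparable clinical samples; the saturating growth law keeps the
  *linear* correlation below 1 even noise-free).
* **Growth**: the newborn template (a half-ellipsoidal shell, semi-axes
  58 x 47 x 47 mm, with anatomically arranged metopic/sagittal/coronal/
  lambdoid/squamosal suture curves) is scaled so its measured polygon
  circumference equals `reference(age) + offset` -- a saturating growth law
  by construction, calibrated exactly in the noise-free limit.
* **Suture closure**: widths follow `max(0, w0 (1 - age/closure))`.
  Default closure ages encode the clinical sequence: squamosal about 7
  months; inferior coronal/lambdoid and metopic about 12; remaining
  coronal/lambdoid and posterior sagittal 14--18; the sagittal segment
  behind the anterior fontanel last, 22--24 months.  Everything is closed
  by 24 months.  A fully closed suture is emitted as a single centerline
  landmark, exactly as a human rater would digitize it.
* **Thickness**: linear in age per label, occipital intercepts and slopes
  above frontal/parietal ones (1.9 mm + 0.075 mm/month occipitally vs
  1.2 mm + 0.055 mm/month frontally -- roughly 1--2 mm at birth and 3--5 mm
  at three years).
* **Noise**: independent Gaussians -- 0.5 mm on coordinates, 0.15 mm on
  widths, 0.08 mm on thickness.  The source reports no per-landmark noise
  model; these are implementer defaults of the order of manual-landmarking
  and CT-resolution error.

A second mode, `model_based`, draws geometries *exactly* from a known
linear-Gaussian shape model (`scores = C f + eps` on hand-built orthonormal
modes that respect the anatomical frame), so PCA-regression recovery can be
tested sharply: with `eps = 0` the fitted model reproduces every training
geometry to machine precision and coefficient error shrinks monotonically
with the residual SD.  In this mode the fitting features are the
generator's own covariates; an offset re-derived from measured
circumference passes through the nonlinear reference curve and would break
the exactly linear structure.  What the generator does **not** emulate:
landmark identification bias, suture interdigitation (fractal suture
boundaries), asymmetry, CT slice-thickness artefacts, and sex differences.
Passing recovery tests therefore demonstrates correctness of the
*estimator*, not clinical validity on real heads.

## Surface reconstruction

Radial basis functions with an affine polynomial term (default kernel
`r^3`; thin-plate and Gaussian offered) interpolate exactly at their nodes
and reproduce affine fields exactly.  Distances are expressed in units of
the mean inter-node spacing before the augmented system is solved -- the
cubic kernel on raw millimetre coordinates is otherwise ill conditioned --
and one step of iterative refinement polishes the solution.
`morph_mesh()` fits the 3D-to-3D RBF map on landmark correspondences and
applies it to a bundled half-ellipsoid template triangulation
(`template_mesh()`; the original template FE mesh is not available);
`thickness_field()` interpolates landmark thickness over the mesh, floored
at 0; `mirror_full_head()` reflects across the mid-sagittal plane without
duplicating points within 1e-6 mm of it, flipping face orientation on the
mirrored half so the seam is watertight.  Occipital-versus-frontal region
membership used in tests is a schema annotation (the source does not define
region boundaries).

## The mixed model

Whether age, circumference and landmark location predict suture width and
skull thickness is tested with a linear mixed model: fixed effects plus a
per-subject random intercept,

$$y_{ij} = x_{ij}^\top\beta + u_i + e_{ij}, \qquad
  u_i \sim N(0, \sigma_u^2),\ e_{ij} \sim N(0, \sigma_e^2).$$

`fit_lmm()` profiles the (RE)ML criterion over the single variance ratio
$\lambda = \sigma_u^2/\sigma_e^2$ (a 1-dimensional optimization with the
boundary $\lambda = 0$ checked explicitly) and obtains the fixed effects by
GLS at the optimum; it matches `lme4::lmer()` to optimizer precision on the
same data.  `anova()` produces Type-III F tests on sum-to-zero contrasts
with **containment** denominator degrees of freedom: effects constant
within subject are tested with `rank([X Z]) - rank(X)` denominator DF,
effects varying within subject with `N - rank([X Z])`.  On a balanced 56 x
32 suture design with all two-way interactions this yields 52 and 1643; on
the 56 x 24 thickness design (no age-by-circumference term) 53 and 1219 --
pure design arithmetic, independent of the responses.  Landmark is a fixed
categorical effect; zero widths of closed sutures stay in the table.

`stepwise_lmm()` does forward selection by ML AIC -- mains first, then
two-way interactions between the significant mains (p < 0.05), hierarchy
respected -- and refits the winner by REML.  AIC entry of a 1-df term under
the null has probability about `pchisq(2, 1, lower = FALSE)` (15.7%); the
tests bound the observed null selection rate by that quantity, and verify
power above 0.9 for an age effect of 0.12 mm/month against 1 mm residual
noise at 15 subjects x 5 landmarks.

## Numerical and design choices

* Tolerances: rigid transforms orthonormal to 1e-8; degenerate (collinear)
  midline configurations rejected at a 1e-8 singular-value ratio; RBF node
  exactness 1e-8; mirroring midline tolerance 1e-6 mm.
* The PCA of a constant block returns zero components with a warning, not
  an error; regression then predicts the constant mean.
* Rank-deficient feature designs (e.g. duplicated columns, or raw
  circumference together with age) raise a collinearity error naming the
  aliased columns -- this is precisely why CirOffset exists.
* Variance components are reported on the natural scale; AIC counts fixed
  effects plus two variance parameters.  Stepwise comparisons always use ML
  fits.
* Problem sizes in the tests are chosen for a desk-scale run: cohorts of
  12--56 subjects, 500-replicate null simulations for test calibration, and
  200-replicate power checks, all seeded.

## Limitations

The model is linear in age, so it over-predicts the newborn head slightly
and cannot represent the saturating growth within the PCA score space
beyond what the cohort's feature range constrains; suture closure enters
only through width magnitudes (no topology change in the model itself); and
all validation is against the synthetic generator -- agreement there shows
the estimators are correct, not that a real 0--36-month population is
captured.  Sex-specific curves, mixture or nonlinear shape models, and
finite-element meshing quality are out of scope.
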