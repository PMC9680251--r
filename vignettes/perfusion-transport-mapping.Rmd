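---
title: "Transport mapping and Kety modeling of DCE-MRI: models, numerics, design"
author: "qtmdce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transport mapping and Kety modeling of DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtmdce)
```

# The problem

Before yttrium-90 radioembolization of a hepatic tumor, clinicians measure
the lung shunt fraction (LSF): the percentage of hepatic arterial input that
bypasses the tumor capillary bed through arterio-venous shunts and reaches
the lungs. The measurement is invasive (catheter-delivered Tc-99m-MAA plus
SPECT). Shunting, however, also shortens transit paths and raises blood
velocity inside the tumor, so perfusion quantities computed from a routine
dynamic contrast-enhanced (DCE) MRI are plausible noninvasive surrogates.
This package implements the two quantification routes that frame that
question — velocity mapping by transport inversion, and classical tracer
kinetics — together with the phantoms and cohort statistics needed to
exercise them end-to-end when patient data are unavailable.

# Models

## Signal to concentration

Tracer concentration is taken proportional to relative enhancement,
$c(\mathbf r, t) = (S(\mathbf r,t) - S_0(\mathbf r))/S_0(\mathbf r)$, with
$S_0$ the mean of the first `baseline_frames` frames (default 1, matching a
five-frame arterial-phase acquisition). This linearity is an approximation;
it degrades at high gadolinium concentration, and nothing downstream
corrects for it. Voxels with nonpositive baseline cannot be normalized:
they are zeroed, flagged, counted, and the series is rejected outright if
they exceed a configurable fraction (default 50 %). Negative concentrations
from noise undershoot are clipped to zero by default because the transport
inversion treats $c$ as a nonnegative density. For phantoms whose tracer is
already present at frame 1 (an advecting bolus has no tracer-free frame) the
conversion accepts a known baseline map instead; real-data processing keeps
the first-frames estimate.

## Transport model and QTM inversion

The transport route models the tracer field by pure advection with a static
velocity field,
$$\partial_t c(\mathbf r, t) = -\nabla\!\cdot\! \big(c(\mathbf r,t)\,\mathbf u(\mathbf r)\big),$$
and estimates $\mathbf u$ (mm/s) voxelwise by

$$\mathbf u = \arg\min_{\mathbf u} \sum_{t=1}^{N_t-1}
\big\lVert \partial_t c + \nabla\!\cdot\!(c\,\mathbf u) \big\rVert_2^2
+ \lambda \lVert \nabla \mathbf u \rVert_1 .$$

No arterial input function enters: each voxel is coupled only to its
neighbors through the flux divergence. Assumptions worth keeping in mind:
the velocity is constant over the acquisition window; there is no diffusion
or exchange term; and the voxel-scale $\mathbf u$ is an average over a
microvascular network, not a plug-flow velocity.

Discretization: forward differences in time between consecutive frames;
central differences of the flux $c_t \mathbf u$ in space, one-sided at the
volume faces (consistent with a closed box). All differences are divided by
the physical spacing (mm, s), so anisotropic voxels — 0.84 mm in-plane
versus 3 mm slices at the default geometry — are handled correctly and
$\mathbf u$ comes out in mm/s.

The TV penalty is anisotropic (axiswise L1 of forward differences, summed
over the three velocity components); the smoothing half-width `tv_eps`
(default $10^{-6}$ (mm/s)/mm, several orders below typical velocity
gradients) makes the objective differentiable without materially moving the
minimizer. The solver is deterministic and first-order: plain conjugate
gradients on the normal equations when $\lambda = 0$ (starting from zero,
hence converging to the minimum-norm least-squares solution), and otherwise
a monotone Barzilai–Borwein descent with backtracking, warm-started from a
truncated CG solve of the data term. The recorded objective never
increases; termination is by relative objective decrease (`tol`) or
`max_iters`, with the reason reported and a warning flag on
non-convergence.

Two numerical behaviors shaped the defaults:

- **Semiconvergence.** Unregularized CG fits genuine transport first and
  discretization error/noise later, so `warm_iters` doubles as mild
  iteration regularization. Deep warm starts (the 2000 default) suit
  noiseless recovery studies; the pipeline uses a shallow 150 for noisy
  phantom data, where deep CG demonstrably inflates the speed map.
- **Uninformative voxels.** Voxels whose temporal variance is at or below
  `var_floor` carry no transport information; they are frozen at
  $\mathbf u = 0$, excluded from the linear system, and flagged so ROI
  statistics can skip them.

The weight $\lambda$ defaults to $10^{-4}$; `l_curve_select()` traces the
(log residual, log TV) curve over a weight grid with ascending-$\lambda$
warm-start continuation and returns the maximum-curvature corner.

## Kety / extended Tofts with delay

The kinetic route models tissue concentration against a global arterial
input function (AIF) $c_a(t)$ extracted as the mean curve over a
feeding-artery mask:
$$\partial_t c = K^{trans}\, c_a(t - \tau) - k_{ep}\, c, \qquad
V_e = K^{trans}/k_{ep},$$
with a travel delay $\tau$ per voxel. As printed sources in this line of
work do, the model carries no plasma-volume term. Rates are in 1/s.

Integrating once gives
$c(t) + k_{ep}\int_0^t c = K^{trans}\int_0^t c_a(s-\tau)\,ds$, which is
linear in $(K^{trans}, k_{ep})$ at fixed $\tau$ and nonlinear in $\tau$
only. The fit therefore alternates:

1. per-voxel exhaustive search of $\tau$ over a grid (default 0–25 s, 1 s
   steps — deterministic, and the update provably cannot increase the
   objective because it only re-picks the best column of a precomputed
   residual table);
2. TV-regularized nonnegative linear solves for the $K^{trans}$ and
   $k_{ep}$ maps at fixed delays (projected Barzilai–Borwein descent;
   weights $\lambda = \mu = 10^{-3}$ by default). With
   $\lambda = \mu = 0$ this collapses to independent per-voxel nonnegative
   least squares via the 2×2 normal equations.

The time integrals use cumulative trapezoids on a time axis upsampled
20-fold, with the measured voxel curves interpolated by natural splines;
the forward simulator uses the same exponential-convolution kernel, so
simulator and fit agree to quadrature accuracy rather than by construction
(delays off the grid and added noise still break the symmetry, which the
tests exploit). $V_e$ is reported only where $k_{ep}$ exceeds a floor of
$10^{-6}$/s; below it $V_e$ is NA, the voxel count is logged, and ROI means
skip those voxels. The identity $V_e \cdot k_{ep} = K^{trans}$ holds
exactly wherever $V_e$ is defined.

# Phantoms: what they emulate, what they do not

`simulate_transport()` integrates the advection equation with a donor-cell
(first-order upwind) flux-form scheme: face fluxes take the upwind voxel's
concentration, boundary faces carry zero flux, so total mass is conserved
exactly and positivity is preserved under the CFL bound
(max |u|·dt/h ≤ 0.5 per axis; substeps are chosen automatically, and an
explicit violation is rejected naming the limiting axis). The cost is
numerical diffusion of order $u h (1-\mathrm{CFL})/2$, which smears sharp
fronts; this is documented rather than corrected, and it is one honest
source of forward/inverse mismatch since the inversion uses central
stencils. A `scheme = "central"` option generates phantoms with exactly the
inversion's stencil for inverse-consistency studies — those quantify solver
behavior free of discretization mismatch, and only those.

`make_aif()` provides the standard gamma-variate bolus (zero before onset,
peak `amplitude` at onset + shape·scale). `synthesize_signal()` applies
$S = S_0 (1 + c)$ plus Gaussian noise of standard deviation
`noise_sd * S0` — noise lives on the signal, not on concentration, because
the conversion is linear. All stochastic steps take explicit seeds and are
bit-reproducible.

The acquisition defaults mirror the clinical protocol this work targets:
0.84 mm in-plane, 3 mm slices, 5 s frames, 5 frames, with a desk-scale
32×32×8 matrix. The source protocol's description is internally ambiguous
about whether five frames span 25 s or the arterial phase lasts only ~5 s;
both `n_frames` and `frame_interval` are therefore explicit parameters
rather than a hard-coded choice.

`generate_cohort()` draws a virtual cohort in which LSF (%) is a noisy
linear function of tumor ROI speed — LSF = 1 + 60·speed + N(0, 3), speeds
uniform on 0.02–0.30 mm/s — chosen so that published group-level speed
values (≈0.08 mm/s low-risk vs ≈0.18 mm/s high-risk) land on the published
side of the 10 % LSF threshold and a 25-patient draw splits roughly evenly.
The remaining columns (Kety parameters, tumor volume ≈ 18.6 ± 15.7 cm³,
age) are drawn independently of LSF from ranges matching published hepatic
cohorts, so a correct analysis must rank speed first. None of this makes
the phantom *real*: there is no motion, no pulse-sequence or relaxivity
physics, no spatial heterogeneity of the link, and the LSF link is linear
by fiat. A green cohort test establishes that the statistics stage
recovers a planted monotone signal — not that DCE MRI predicts LSF in
patients.

In the full phantom pipeline each virtual patient carries a corner artery
region whose voxels are overwritten with the AIF curve. That region
violates mass conservation by construction (its tracer appears from
nowhere), and if left in the field it contaminates the velocity map far
beyond its footprint. The pipeline therefore zeroes the artery region in
the concentration passed to the transport inversion — the digital analogue
of large-vessel exclusion before tissue perfusion analysis — while the Kety
stage keeps it, since it exists precisely to supply the AIF.

# Statistics

The cohort stage mirrors the analysis plan of the clinical study this
package is built around: split at LSF 10 % (boundary inclusive to the
low-risk group); Spearman correlation of each of six parameters (speed,
$K^{trans}$, $V_e$, $\tau$, tumor volume, age) with LSF; Mann–Whitney U
between risk groups for the four perfusion parameters; ROC per parameter.

- **Spearman significance** uses $F = (n-2)r^2/(1-r^2)$ on $F(1, n-2)$.
  This transform was chosen because it reproduces the published F values
  from the published correlation coefficients at $n = 25$ to within
  rounding, which pins down the construction actually used. The 95 % CI
  uses the Fisher z-transform; published CIs in the source table are
  symmetric around r and match neither Fisher-z nor the asymptotic
  standard error, so the CI method is flagged as a documented default
  rather than a reproduction. An exact permutation p-value is available
  for n ≤ 8.
- **Mann–Whitney U** is oriented as high-over-low pairs so that
  $U/(n_1 n_2)$ equals the ROC AUC exactly on tie-free data. The p-value
  is exact (distribution enumeration) for $n_1 n_2 \le 400$ without ties,
  otherwise normal with tie and continuity corrections.
- **ROC** uses the rank formulation with half-credit ties; CIs are
  stratified bootstrap percentiles (2000 seeded resamples by default) —
  the source's CI method is unstated and its asymmetric intervals are not
  reproducible without patient-level data. The operating threshold
  maximizes sensitivity + specificity, ties resolved toward the lower
  threshold; an AUC below 0.5 is flagged, never silently flipped.
- **DeLong** compares paired AUCs via placement-value covariance. It is an
  asymptotic z-test: at n ≈ 20 it tracks an exact permutation oracle to a
  few hundredths in p, which is the agreement the test suite asserts.

All tests are two-sided with significance at p ≤ 0.05.

# Numerical choices and degenerate inputs

- Objective traces (QTM, Kety) are non-increasing by construction
  (backtracking, and τ re-selection from a residual table); tests assert
  this to 1e-10 relative.
- The λ = 0 QTM solution matches a dense pseudoinverse oracle to 1e-6
  relative on small grids; the scaling identity
  solve(αc, α²λ) = solve(c, λ) holds exactly for power-of-two α (floating
  point commutes with those) and to solver tolerance otherwise.
- Degenerate inputs fail loudly with named causes: empty masks, all-zero
  AIF (model unidentifiable), τ grids beyond the acquisition window, CFL
  violations (naming the axis), non-4D series (naming the dimensionality),
  missing per-patient files (naming the patient and stage). A
  zero-variance cohort column yields an NA report row rather than aborting
  the other parameters.
- Ties: average ranks throughout; ROC threshold ties toward the lower
  value; τ grid-search ties toward the smaller delay.

# Known limitations

- First-order upwind diffusion biases long phantom integrations; a
  higher-order limiter scheme would narrow the forward/inverse gap.
- The velocity field is static and divergence is the only transport
  mechanism; perfusion exchange and diffusion are absorbed into an
  effective $\mathbf u$.
- Kety fitting assumes the AIF is measured on the same relative-enhancement
  scale as tissue (no partial-volume or inflow correction).
- The published patient-level results (r = 0.6156 with LSF, AUC = 0.87)
  are not reproducible here: the 25-patient dataset is available only on
  request, so the cohort-level checks run on synthetic cohorts whose
  ground truth is planted. Closed-form quantities that depend only on
  published numbers (the Spearman F column) are reproduced exactly.
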