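# qtmdce

Quantitative perfusion processing of dynamic contrast-enhanced (DCE) MRI for
liver tumors, aimed at the question of whether noninvasive perfusion
parameters can stand in for the invasive lung shunt fraction (LSF)
measurement that precedes yttrium-90 (Y90) radioembolization. Today LSF is
measured by catheter-delivered Tc-99m-MAA and SPECT; tumors with heavy
arterio-venous shunting also show faster blood transit, so perfusion
quantities computed from a routine DCE acquisition are candidate predictors.

The package implements two voxelwise quantification routes and the cohort
statistics connecting them to LSF:

- **Quantitative transport mapping (QTM).** The tracer field c(r, t) is
  modeled by the advection equation with a static velocity field,
  ∂ₜc = −∇·(c **u**). The inverse problem

  **u** = argmin  Σₜ ‖∂ₜc + ∇·(c **u**)‖₂² + λ‖∇**u**‖₁

  is solved by TV-regularized least squares (anisotropic TV; λ = 10⁻⁴ by
  default, selectable by the L-curve). No arterial input function is
  required; the speed map |**u**| (mm/s) is the headline readout.
- **Delay-fitted Kety / extended Tofts.** With an arterial input function
  ca(t) drawn from a feeding-artery mask, ∂ₜc = Kᵗʳᵃⁿˢ·ca(t − τ) − kₑₚ·c is
  fitted voxelwise for Kᵗʳᵃⁿˢ, kₑₚ, Vₑ = Kᵗʳᵃⁿˢ/kₑₚ and the bolus delay τ
  (exhaustive τ grid search alternating with TV-regularized nonnegative
  linear solves; λ = μ = 10⁻³ by default).
- **Cohort statistics.** Risk split at LSF 10 %, Spearman correlation with
  F = (n−2)r²/(1−r²) significance, Mann-Whitney U (exact for small
  samples), ROC with stratified-bootstrap CIs and Youden thresholds, and
  the paired DeLong test between AUCs.

Because patient DCE/SPECT data are not public, the package ships digital
phantoms: a mass-conserving upwind advection simulator, an
exponential-convolution Kety simulator with gamma-variate input functions,
a linear-enhancement signal model with Gaussian noise, and a virtual-cohort
generator in which LSF is a noisy monotone function of tumor ROI speed.
Volumes move as NIfTI-1 (+ JSON sidecar); cohort tables as CSV.

## Worked example

Recover a known constant velocity from a noiseless transport phantom at the
clinical geometry (0.84 × 0.84 × 3 mm voxels, 5 frames at 5 s):

```r
library(qtmdce)

g  <- volume_grid(c(32, 32, 8))               # clinical spacing defaults
c0 <- gaussian_blob(g, sigma_mm = c(4, 4, 4))
cs <- simulate_transport(c0, constant_velocity(c(0.08, 0.06, 0), g), g)
fit <- solve_qtm(cs, qtm_config(lambda = 1e-6, max_iters = 1500,
                                warm_iters = 2000, tol = 1e-11))
roi_mean(fit$speed, roi_mask(c0 > 0.05 * max(c0)))$mean
#> ROI mean |u| = 0.1021 mm/s            (ground truth 0.1000 mm/s)
```

Then relate perfusion parameters to LSF on a 25-patient virtual cohort in
which only ROI speed carries LSF signal:

```r
co  <- generate_cohort(n = 25, seed = 7)
rep <- build_report(co, boot_n = 2000, seed = 7)
rep
#> Cohort report (LSF split at 10%: 14 low / 11 high)
#>
#> Spearman correlation with LSF:
#>     parameter         r   f_value         p
#>       QTM |u|  0.926154 1.387e+02 3.210e-11
#>        Ktrans -0.273846 1.865e+00 1.853e-01
#>            Ve  0.056923 7.477e-02 7.870e-01
#>           tau -0.308462 2.419e+00 1.336e-01
#>  Tumor volume -0.203077 9.893e-01 3.303e-01
#>           Age  0.008873 1.811e-03 9.664e-01
#>
#> ROC (high-risk classification):
#>     parameter   auc ci_low ci_high sensitivity specificity
#>       QTM |u| 0.968 0.8961   1.000       0.818      1.0000
#>        Ktrans 0.455 0.2273   0.688       0.727      0.4286
#>  ...
```

The speed map dominates both rankings, as it must when the cohort's LSF is
generated from speed alone: r = 0.93 (F = 138.7) against the next-best
|r| = 0.31, and AUC = 0.97 against 0.55. `write_report()` renders the same
tables to `table1.csv`, `table2.csv` and `groups.csv`.

An end-to-end run — phantom patients through signal conversion, QTM, Kety,
ROI summarization and statistics — is one call:

```r
res <- run_pipeline(pipeline_config(mode = "phantom", n_patients = 8,
                                    seed = 1, output_dir = "out"))
```

`inst/cli/qtmdce.R` exposes the same stages as shell subcommands
(`phantom`, `qtm`, `kety`, `roi`, `stats`, `run`).

## Sidecar schema

`save_series()` writes, next to each `.nii`/`.nii.gz` volume, a JSON
sidecar with `spacing_mm`, `frame_interval_s`, `n_frames`, plus any
caller-supplied fields (seed, ground-truth parameters). On load the sidecar
frame interval overrides the NIfTI header time step; mismatches are
reported.

## Acceptance script

`scripts/acceptance.R` re-runs the full phantom pipeline from scratch
against the installed package and writes its JSON result file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
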