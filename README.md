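# anisofmri

Paradigm-free recovery of activity-inducing signals from 4D fMRI by
anisotropic diffusion on the joint space–time volume.

## What problem this solves, and for whom

BOLD fMRI observes neural activity only through the hemodynamic response:
an activity-inducing signal `u(v, t)` is convolved with the HRF `h(t)` and
buried in noise, giving the acquired series `y(v, t)`.  Task analyses (the
GLM) need the experimental paradigm to build regressors; for resting-state
data, clinical populations who cannot perform tasks, or unpredictable
events such as epileptic discharges, no paradigm exists.  This package is
for neuroimaging researchers who want to recover the location and timing of
activations from the 4D image alone.

## The method

The recovered image is the end state of an explicit finite-difference flow
acting simultaneously on the three spatial axes and the temporal axis,

```
dI/dt = (1 - alpha) * H'(I0 - H I) / ||I0||_2
      +      alpha  * div(D~ grad I) / ||div(D~0 grad I0)||_2
```

where `H` is causal convolution with the HRF along time (with adjoint `H'`),
and `D~` is a per-voxel 4x4 steering tensor built from the Gaussian-smoothed
structure tensor `D = (grad I grad I' / ||grad I||) * G(sigma_g)`: after the
eigendecomposition `D = Q L Q'`, the leading eigenvalue is remapped to

```
l1~ = exp( -(l1 / max L)^2 / (2 sigma_d^2) ),    l2~ = l3~ = l4~ = 1
```

(`max L` taken over all voxels) and the tensor rebuilt as `D~ = Q L~ Q'`.
Strong gradients — activation onsets, spatial edges — almost stop diffusion
across their direction; flat regions smooth isotropically in x, y, z and t.
Defaults: `alpha = 0.9997`, `sigma_g = 1` voxel, `sigma_d = 0.2`,
`step = 0.1`, 40 iterations.  See the methods vignette
(`vignettes/anisotropic-fmri-regularization.Rmd`) for assumptions,
numerical choices and known limitations.

The package also ships the synthetic BOLD phantom used for validation
(block/spike designs, amplitude map in [0, 3], two-stage Gaussian noise,
HRF convolution, pSNR calibration), evaluation metrics (voxel-wise Pearson
maps, RMSE summaries, spherical MNI ROIs with a packaged somatosensory
center table), NIfTI-1 I/O with detrend + z-score preprocessing, and a
small CLI.

## Worked example

```r
library(anisofmri)

# 1. Simulate a 12x12x12 x 100 s phantom: boxcar activation 20-60 s,
#    acquisition noise calibrated to 6.5 dB peak-SNR
spec <- phantom_spec(target_psnr = 6.5, seed = 42)
ds <- synthesize_phantom(spec)
psnr(ds$x, ds$y)
#> [1] 6.491161

# 2. Recover the activity-inducing signal with the default flow
res <- run_flow(ds$y, ds$kernel, flow_config())
res
#> <flow_result> 12x12x12x100 grid, 40 iterations (alpha = 0.9997,
#>   sigma_g = 1, sigma_d = 0.2, step = 0.1)

# 3. Compare against the ground truth over the gray-matter mask
before <- phantom_metrics(ds$y, ds$u, ds$gm_mask)
after  <- phantom_metrics(res$u_hat, ds$u, ds$gm_mask)
round(c(r_raw = before$r_mean, r_recovered = after$r_mean,
        rmse_raw = before$rmse, rmse_recovered = after$rmse), 4)
#>          r_raw    r_recovered       rmse_raw rmse_recovered
#>         0.2263         0.2266         8.4591         8.4500

tail(res$diagnostics, 3)
#>    iteration fidelity_l2 regularization_l2 lambda1_max
#> 38        38    10.33429         0.9988534    18.87218
#> 39        39    10.33407         0.9988225    18.87197
#> 40        40    10.33386         0.9987915    18.87176
```

The recovered image correlates better with the ground-truth activation than
the raw acquisition does, and its error is lower — the flow denoises while
preserving the activation structure.  At the default `alpha` the margins
are small: the update is dominated by the diffusion term and normalized by
frozen whole-image constants, so 40 steps change the image slowly (the
per-iteration term norms in the diagnostics stay near 1 by construction).
The vignette discusses this regime and the `normalization = "voxelwise"`
option that makes updates proportionally larger.

The same pipeline from the shell:

```sh
Rscript exec/anisofmri simulate --out-dir sim --seed 42 --target-psnr 6.5
Rscript exec/anisofmri filter   --in sim/y.nii.gz --out uhat.nii.gz \
                                --diagnostics diag.tsv
Rscript exec/anisofmri evaluate --in uhat.nii.gz --truth sim/u.txt \
                                --mask sim/gm_mask.nii.gz
```

Every run writes a JSON manifest; `rerun --manifest <file>` reproduces the
outputs bit-identically.

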