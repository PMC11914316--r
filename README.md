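# mwijoint

Myelin water fraction (MWF) mapping from multi-echo MRI by **joint
inversion** of gradient-echo and spin-echo decay data.

## The problem

Myelin water — the water trapped between myelin sheaths — relaxes faster
than axonal/extracellular water, and its fractional contribution

$$\mathrm{MWF} = \frac{I_1}{I_1 + I_2}$$

is an indirect MRI marker of brain myelin content. It is estimated from
multi-echo spin-echo (ME-SE, sampling the multi-exponential $T_2$ decay)
or multi-echo gradient-echo (ME-GE, sampling $T_2^*$) data. Recovering a
relaxation spectrum from its decay is an inverse-Laplace-type problem:
ill-posed, noise-amplified, and under-determined, so single-dataset
estimates are biased by the regularization they need to be stable.

`mwijoint` models each spectrum as a two-pool **bi-Gaussian**
distribution — myelin water pool $(\mu_1, \sigma_1, I_1)$ and
axonal/extracellular pool $(\mu_2, \sigma_2, I_2)$, with
$I_1 = I_2\,\mathrm{MWF}/(1-\mathrm{MWF})$ so that MWF is itself a model
parameter — and fits:

* **SE**: 6 $T_2$ parameters against the ME-SE magnitude decay, with an
  extended-phase-graph (EPG) CPMG forward model that accounts for
  stimulated echoes at non-ideal (B1-scaled) refocusing angles;
* **GE**: 6 ($T_2^*$, magnitude model) or 9 (complex model with
  per-pool frequency shifts $\Delta\omega_1, \Delta\omega_2$ and a
  constant phase $\Phi_0$) parameters against the ME-GE decay;
* **JOINT**: all 14 parameters against both datasets simultaneously,
  sharing a single MWF — the complementary $T_2$ / $T_2^*$ information
  makes the inversion less ill-posed and the MWF estimate more accurate.

Each voxel is solved by a damped, bound-constrained Levenberg–Marquardt
iteration (finite-difference Jacobians; exact active-set bounded linear
subproblems) minimizing

$$\alpha\lVert S_{SE}-\hat S_{SE}(x)\rVert^2 +
\lVert S_{GE}-\hat S_{GE}(x)\rVert^2 +
\lVert\lambda\circ(x-x_{in})/w\rVert^2 ,$$

a data misfit on first-echo-normalized signals plus a penalty pulling
the model towards its initial values (scaled by the bound widths $w$;
$\alpha = 2$ balances the real SE rows against the complex GE rows).
A seeded phantom simulator reproduces the validation study — two-pool
spectra per voxel of an MWF map, forward signals, complex Gaussian noise
at a first-echo SNR of 150 — with full ground truth for recovery
testing. See the vignette `joint-myelin-water-inversion` for the model,
the discretization scheme, and every numerical choice.

## Worked example

Simulate a phantom study and compare the three inversions:

```r
library(mwijoint)

phantom <- make_phantom(c(24, 24), "blocks", seed = 1, n_regions = 4)
run     <- draw_run_parameters(seed = 1)   # spectral truth for this run
dataset <- simulate_dataset(phantom, run, snr = 150, seed_noise = 1)

b1 <- array(1, dim(phantom$mwf))           # flat relative-B1 map
fits <- list(
  joint = fit_volume(dataset, default_config("JOINT",   "simulation"), b1 = b1),
  se    = fit_volume(dataset, default_config("SE",      "simulation"), b1 = b1),
  ge    = fit_volume(dataset, default_config("GE_CPLX", "simulation"), b1 = b1)
)
dplyr::bind_rows(lapply(fits, glance))
```

```
# A tibble: 3 × 8
  mode    n_voxels prop_converged median_iter mean_cost mwf_bias mwf_mae mwf_rmse
  <chr>      <int>          <dbl>       <int>     <dbl>    <dbl>   <dbl>    <dbl>
1 JOINT        115        0.00870          50  0.00446   0.00580  0.0170   0.0235
2 SE           115        0.278            50  0.000877  0.00728  0.0244   0.0343
3 GE_CPLX      115        0.0261           50  0.00267   0.00706  0.0311   0.0397
```

The 115 phantom voxels carry true MWF values between 0.05 and 0.30.
`mwf_mae` is the voxel-wise mean absolute error of the fitted MWF
against that truth: the joint inversion (0.017) is closer to the ground
truth than either single inversion (SE 0.024, complex GE 0.031) at this
noise level, which is the method's core claim. (`prop_converged` counts
voxels that met the strict internal tolerances before the 50-iteration
cap; noisy voxels routinely stop at the cap with a long-stable
estimate.) Per-region statistics of any fitted parameter come from
`roi_stats()`:

```r
labels <- (phantom$mwf > 0.15) * 1L        # a toy ROI
roi_stats(fits$joint, labels, names = c(`1` = "high-mwf"),
          parameters = c("mwf", "mu1_t2", "mu2_t2s"))
```

```
# A tibble: 3 × 6
  roi      label parameter n_voxels   mean     sd
1 high-mwf     1 mu1_t2          45 17.8   3.16
2 high-mwf     1 mu2_t2s         45 61.4   1.99
3 high-mwf     1 mwf             45  0.246 0.0493
```

The fitted myelin-pool $T_2$ mean (17.8 ms) and AEW $T_2^*$ mean
(61.4 ms) sit next to this run's drawn truths; `autoplot(fits$joint)`
maps the fitted MWF and `plot_mwf_scatter(fits)` draws the
estimated-versus-true scatter. `tidy()` returns one row per voxel and
parameter for further analysis.

Everything is also scriptable from a shell via `inst/cli/mwijoint.R`
(`simulate | fit | evaluate`), which writes NIfTI volumes, JSON sidecars
and run manifests.

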