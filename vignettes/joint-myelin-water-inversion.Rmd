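---
title: "Joint inversion of multi-echo gradient-echo and spin-echo data for myelin water mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint inversion of multi-echo gradient-echo and spin-echo data for myelin water mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Water trapped between myelin sheaths (myelin water, MW) relaxes faster than
axonal and extracellular water (AEW). The myelin water fraction,

$$\mathrm{MWF} = \frac{I_1}{I_1 + I_2},$$

with $I_1$ and $I_2$ the pool integrals of the MW and AEW components,
is an indirect marker of myelin content. Multi-echo spin-echo (ME-SE) data
sample the $T_2$ decay and multi-echo gradient-echo (ME-GE) data the
$T_2^*$ decay of the same voxel; both are superpositions of many decaying
components. Estimating a relaxation spectrum from its multi-exponential
decay is an inverse-Laplace-type problem: severely ill-posed, noise
amplified, and usually under-determined. `mwijoint` implements a
parametric two-pool approach in which each spectrum is a sum of two
Gaussians, and — its central idea — a *joint* inversion in which one MWF
parameter is shared between the $T_2$ and the $T_2^*$ spectrum, so that
two partially independent datasets constrain the quantity of interest
simultaneously.

## Signal models

**Spin echo.** Refocusing pulses in a CPMG train are never exactly
180°, in vivo, so stimulated-echo pathways contribute to every echo. The
SE kernel is therefore computed with the extended phase graph (EPG)
algorithm (`epg_cpmg_signal()`): ideal 90° excitation under the CPMG
phase condition, hard refocusing pulses at the effective angle
$\alpha_r$ (nominal angle × relative B1), $T_1$/$T_2$ relaxation over
each half echo spacing, and ideal crusher dephasing expressed by the EPG
configuration-order shift. All `etl + 1` coherence orders are retained,
so there is no truncation error; at $\alpha_r = 180^\circ$ the kernel
collapses to $e^{-t/T_2}$ exactly. The $T_1$ dependence is weak for
brain tissue ($T_1 \gg T_2$) and a fixed $T_1 = 1000$ ms is used by
default. The kernel is validated against a 10,000-spin isochromat Bloch
simulation (hard pulses, exponential relaxation, ideal crushers), which
agrees to machine precision at every tested flip angle.

**Gradient echo.** The GE kernel is plain exponential decay in $T_2^*$,
extended to a complex model in which the MW and AEW pools carry constant
frequency offsets $\Delta\omega_1, \Delta\omega_2$ (in Hz; the phase
accrual is $2\pi\,\Delta\omega\,t$) and the voxel a constant phase
offset $\Phi_0$:

$$\hat S_{GE}(t) = \left[Q_1(t)\,e^{i 2\pi \Delta\omega_1 t}
 + Q_2(t)\,e^{i 2\pi \Delta\omega_2 t}\right] e^{i\Phi_0},$$

where $Q_c(t)$ is the real decay transform of pool $c$'s Gaussian
$T_2^*$ distribution. Because the frequency shift is attached per pool
rather than per relaxation-time grid point, applying the decay operator
per pool and multiplying the phase factors afterwards is exact, not an
approximation. A magnitude-only variant (`ge_forward_magnitude()`)
drops the shifts and phase; it exists because fitting magnitude GE data
with a purely real model is the common simpler alternative, and the
package reproduces the comparison between the two.

## Discretizing the spectra

Both forward models act on spectra discretized over a log-spaced
relaxation-time grid, so that the expensive SE kernel can be precomputed
once per echo-train description (`build_se_operator()`) and reused for a
whole volume. Defaults: 360 log-spaced nodes on [0.2, 400] ms. The lower
limit is chosen where every acquired echo time gives a numerically zero
kernel, so Gaussian tail mass clipped at the grid floor cannot influence
any signal; the node count keeps the per-decade resolution at the level
needed for the accuracy targets below.

Binning is mass-preserving and second-order accurate: each grid cell
(bounded by geometric edge midpoints, outer edges open) receives the
exact Gaussian probability mass of the cell, and that mass is deposited
onto the three nearest nodes such that the cell's zeroth, first and
second moments are reproduced. Plain nearest-node binning would quantize
the *location* of a narrow Gaussian (the fitted widths start at
$\sigma = 0.1$ ms, far below the cell width) to the grid, producing
relative forward errors of order $10^{-2}$; moment-matched deposition
removes both the location and the curvature error, and the forwards
agree with adaptive quadrature of the continuous integrals to better
than $10^{-4}$ relative error over the entire feasible parameter box
(tested). Deposition weights can be marginally negative, as with any
higher-order scheme; masses still sum exactly, and the deposited
variance is capped at the node-triple scale so boundary cells that
absorb clipped tail mass cannot produce oscillating weights.

## The inversion

Per voxel the package minimizes, over the box-constrained model vector
$x$,

$$\alpha\,\lVert S_{SE} - \hat S_{SE}(x)\rVert^2
 + \lVert S_{GE} - \hat S_{GE}(x)\rVert^2
 + \lVert \lambda \circ (x - x_{in}) / w \rVert^2,$$

where the first term is dropped (and $\alpha$ with it) for single-GE
fits, the second for single-SE fits, $w$ is the vector of bound widths,
and complex GE residuals enter as separate real and imaginary rows. The
SE weight defaults to $\alpha = 2$ because the complex GE block carries
twice as many rows (magnitude and phase information) as the
magnitude-only SE block. Signals must be first-echo normalized
($|S(TE_{min})| = 1$), which makes every fitted parameter invariant
under global rescaling of the raw data; the pool integrals are then in
normalized units.

**Regularization scaling.** The penalty pulls the solution towards the
initial model $x_{in}$ rather than towards zero — the means are anchored
at literature values, the widths at the near-delta initialization. The
deviations are scaled by the bound widths before $\lambda$ multiplies
them. This is a deliberate design choice: with raw-unit deviations a
$\lambda$ of 0.01 on a mean parameter whose natural excursions are tens
of ms contributes a squared penalty comparable to the whole normalized
data misfit, and the noise-free optimum is visibly biased (MWF off by
~0.07 in direct experiments). Width-scaled deviations make $\lambda$
dimensionless and comparable across parameters, and noise-free joint
inversion then recovers MWF to ±0.005 and all Gaussian means to under
1 ms, which is the behavior the method is designed to have.

**Optimizer.** A damped Levenberg–Marquardt iteration: finite-difference
Jacobian (step $10^{-4}$ of the bound width, reflected at the upper
bound; the linear regularizer rows are set analytically), then the
bounded linear subproblem

$$\min_d \lVert J d + r \rVert^2 + \mathrm{damping}\,\lVert d/w \rVert^2,
 \quad l - x \le d \le u - x,$$

solved exactly by an in-package active-set bounded-variable least-squares
routine (`bvls()`, validated against `optim(method = "L-BFGS-B")` on the
same quadratics). Steps that fail to decrease the cost escalate the
damping tenfold (up to five retries per iteration, reusing the
Jacobian); accepted steps relax it back towards the base value of 0.01.
Iteration stops at `max_iter = 50`, at a relative cost decrease below
$10^{-10}$, or at a scaled step norm below $10^{-8}$; the best visited
point is returned, so the reported cost never exceeds the cost of the
initial model. The optimizer contains no randomness. All-zero or
non-finite voxels short-circuit with `status = "degenerate_input"`.

Because a finite-difference Jacobian perturbs one parameter at a time,
and each shape parameter touches exactly one Gaussian pool while the
integrals, MWF, shifts and phase are analytic scalers, the evaluator
caches the four per-pool unit signals and recomputes only the pool a
column actually changes. This makes volume fitting tractable in pure R.

**Phase initialization.** $\Phi_0$ is bounded on $[0, 2\pi]$ and, by
default, initialized per voxel at the phase of the first GE echo
(`phi0_init = "first_echo_phase"`), with the regularization anchor moved
accordingly. The phase accrued by $TE_1 = 2$ ms of frequency shift is
negligible, so the first-echo phase essentially *is* $\Phi_0$; starting
at a fixed 0 instead intermittently drops the fit into a basin where
large spurious frequency shifts absorb the missing phase and the
amplitude collapses (observed on roughly one in five random truths with
$\Phi_0 > \pi/2$). Setting `phi0_init = "fixed"` restores the plain
fixed initialization.

**Parameter table.** Initial values and bounds follow the two-pool
literature values built into `model_parameter_table()`. One printed
value was corrected after it proved internally inconsistent: the lower
bound of the AEW $T_2^*$ mean is 45 ms (matching the AEW $T_2$ bound),
not 55 ms — the study's own simulation range for that mean extends down
to 48 ms, which a 55 ms bound could never recover. MWF is itself a model
parameter (bounds [0, 0.85]); the MW integral is always derived as
$I_1 = I_2\,\mathrm{MWF}/(1-\mathrm{MWF})$. The joint model imposes no
explicit $T_2^* \le T_2$ constraint; with realistic data the forward
models enforce it implicitly.

## The synthetic study

`make_phantom()` builds a deterministic, seeded 2-D MWF map:
piecewise-constant rectangular regions with MWF between 0.05 and 0.30 on
a zero background (background voxels are flagged and excluded from
fitting), mimicking the discontinuous value range of a white-matter
atlas slice; a user-supplied MWF map can be substituted. For each
simulation run, `draw_run_parameters()` draws the spectral shape
parameters uniformly from the study ranges ($\mu_{1,T_2} \in [16,22]$,
$\mu_{2,T_2} \in [65,80]$, $\mu_{1,T_2^*} \in [10,15]$,
$\mu_{2,T_2^*} \in [48,62]$ ms, all $\sigma \in [0.2,1]$ ms,
$\Delta\omega_1 \in [-10,-2]$ Hz, $\Delta\omega_2 \in [-3,3]$ Hz,
$\Phi_0 \in [0,\pi]$), which by construction keep $T_2^* \le T_2$ per
pool. The pool integrals are held at $I_{2,T_2} = 2$ and
$I_{2,T_2^*} = 1$ — the model's initial values, a choice made once since
no specific constants are prescribed — and rescaled per voxel so the
myelin/total ratio matches the phantom MWF. `simulate_dataset()`
evaluates both forwards (in-vivo protocol by default: 24 spin echoes at
6.6 ms spacing with nominal 180° refocusing; 32 gradient echoes at
exponentially increasing spacing, $TE_0 = 2$ ms, $\Delta TE_0 = 1.5$ ms,
rate 0.02), adds complex Gaussian noise with per-channel standard
deviation $|S(TE_1)|/\mathrm{SNR}$ (default SNR 150), takes magnitudes
for the SE volumes (Rician), and keeps the GE volumes complex.
Everything is reproducible from three seeds (phantom, run, noise);
changing only the noise seed changes the data but not the truth.

What the generator deliberately does *not* emulate: $B_0$
inhomogeneity and phase wraps, orientation-dependent frequency shifts,
exchange between pools, partial-volume mixing beyond the two pools,
motion, and coil effects. Passing recovery tests on these data therefore
demonstrates the correctness and conditioning of the inversion, not
robustness to real-scanner confounds — data simulated and fitted with
the same parametric family are the favorable case for a parametric
inverter (the "inverse crime"), which is also why no NNLS baseline is
simulated here: it would be structurally disadvantaged by construction.

## Pipeline and evaluation

`fit_volume()` applies the inversion voxel-wise under a mask, scales the
nominal refocusing angle by a relative-B1 map (quantized to 0.01 steps
so the EPG operator is rebuilt once per distinct value, an error bounded
by the smoothness of the EPG kernel in $\alpha_r$), normalizes each
voxel, and returns a tibble of per-voxel estimates with `tidy()`,
`glance()` and `autoplot()` methods. `phase_match_repeats()` removes the
TE-linear phase drift between repeated GE scans (voxel-wise unwrap and
least-squares line fit) so repeats can be complex-averaged.
`error_maps()` produces signed difference maps with bias/MAE/RMSE, and
`roi_stats()` per-ROI means and sample (n−1) standard deviations in
native voxel space, from an integer label volume — atlas warping and
registration are upstream of this package. `cmd_simulate()`,
`cmd_fit()` and `cmd_evaluate()` (plus the `inst/cli/mwijoint.R`
wrapper) tie these into reproducible, manifest-tracked runs.

## Problem sizes and test design

The bundled tests run the complete study at desk scale: a 32 × 32
phantom with six regions (144 fitted voxels), two simulation runs at
SNR 150, joint and both single inversions with the flat simulation
regularization ($\lambda = 0.01$, $\alpha = 2$), asserting that the
voxel-wise mean absolute MWF error of the joint inversion does not
exceed that of either single inversion, and that the complex GE model
beats the magnitude-only GE model on data carrying frequency shifts.
Noise-free recovery is checked on 20 random truths (MWF within ±0.005,
all Gaussian means within 1 ms). Forward-model accuracy is asserted
against adaptive quadrature (20 random feasible models, $10^{-4}$
relative), the EPG kernel against the isochromat oracle ($10^{-4}$
relative, achieved at ~$10^{-15}$), and the bounded solver against
`optim`. These sizes are the package's chosen compromise between
statistical stability of the ensemble assertions and a test suite that
runs in minutes.

## Known limitations

* Local search only: one start per voxel (plus the data-driven phase
  start); no multi-start or global optimization, no uncertainty
  quantification.
* The two-pool Gaussian family is an assumption; spectra with more
  compartments or heavy tails are projected onto it.
* Convergence at 50 iterations is intentionally strict-tolerance /
  capped-iterations; noisy voxels typically stop at the iteration cap
  with `converged = FALSE` even though the estimate has long stabilized
  — inspect `cost` and the error metrics rather than the flag alone.
* In-vivo confounds listed above are out of the simulator's scope, and
  results on synthetic data should be read accordingly.
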