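---
title: "Methods: FCS binding dynamics and 3D nuclear morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FCS binding dynamics and 3D nuclear morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`fcsmorph` implements two quantitative analyses of transcription-factor (TF)
behavior in live-cell nuclei: (i) single-point fluorescence correlation
spectroscopy (FCS) of a fluorescently tagged TF, fitted with a diffusion plus
two-binding-population autocorrelation model to recover the free,
short-lived-bound and long-lived-bound fractions and their residence times;
and (ii) 3D morphometry of confocal nucleus stacks — denoising, segmentation,
and per-nucleus volume and sphericity — with bootstrap median tests for
treatment-versus-control comparisons. A synthetic-data layer generates photon
traces, model-derived autocorrelation curves, and voxelized nuclei with known
ground truth, so the whole chain is testable without any external data.

## The autocorrelation model

The normalized fluctuation autocorrelation of the fluorescence collected from
a 3D Gaussian observation volume is modeled as

$$ G(\tau)=\frac{1}{2^{3/2}N}\left[f_D\left(1+\frac{\tau}{\tau_D}\right)^{-1}
\left(1+\frac{\tau}{\omega^2\tau_D}\right)^{-1/2}
+ f_{\mathrm{short}}\,e^{-\tau/\tau_{\mathrm{short}}}
+ f_{\mathrm{long}}\,e^{-\tau/\tau_{\mathrm{long}}}\right] $$

where $N$ is the mean number of fluorescent molecules in the confocal volume,
$\tau_D$ the characteristic diffusion time, $\omega = w_z/w_r$ the
axial-to-radial waist ratio, $f_D$ the freely diffusing fraction, and
$f_{\mathrm{short}}, f_{\mathrm{long}}$ the fractions bound to short- and
long-lived chromatin targets with residence times $\tau_{\mathrm{short}} <
\tau_{\mathrm{long}}$; the dissociation rate of each class is
$k_{\mathrm{off}} = 1/\tau$. The model assumes binding sites are immobile
(bound molecules contribute pure exponentials), binding and diffusion
timescales separate, and no photophysics (no triplet blinking, bleaching, or
afterpulsing terms).

Model conventions adopted here, where the model statement itself is silent:

* **Fractions live on the simplex** $f_D+f_{\mathrm{short}}+f_{\mathrm{long}}=1$.
  Reported complementary changes in fractions are only well defined under
  this constraint, and the fitter enforces it exactly (softmax
  parameterization).
* **$\omega$ is a calibration input, never fitted** (default 5, a typical
  confocal value). $\omega$ and $\tau_D$ are strongly degenerate; fitting
  both is unstable.
* **Amplitude convention.** We define the generator's $N$ as the occupancy of
  the $e^{-2}$ focal volume $V_{\mathrm{eff}} = \pi^{3/2} w_r^2 w_z$ (so the
  mean count rate is $\varepsilon N / 2^{3/2}$ for brightness
  $\varepsilon$). The exact zero-lag amplitude of the fluctuation ACF is
  $1/(C\,\pi^{3/2} w_r^2 w_z)$, so the $N$ appearing in the model prefactor
  $1/(2^{3/2}N)$ — the quantity the fitter reports — equals the
  $V_{\mathrm{eff}}$ occupancy divided by $2^{3/2}$ (the 3D-Gaussian shape
  factor folded into the amplitude). `implied_fcs_params()` reports ground
  truth in the model convention so that simulate → correlate → fit is a
  fixed point of the parameter set.

## The correlator

`autocorrelate()` estimates $G(\tau)$ with the symmetric (lag-matched mean)
normalization, $G(k) = \sum_i F_i F_{i+k} / ((n-k)\,m_1 m_2) - 1$, the
standard finite-trace bias correction. Only $\tau > 0$ is reported; the
zero-lag channel is dominated by shot noise and excluded from fitting.

The `multi_tau` scheme uses the classic multi-tau lag layout — $m = 16$
linearly spaced lags per stage with the spacing doubling between stages — but
evaluates **every lag at full bin resolution** (compiled code) rather than on
progressively coarsened registers. Register coarsening is a memory-saving
device for streaming hardware; on an in-memory binned trace it triangularly
smears neighboring lags and makes the estimate deviate from the brute-force
estimator in finite samples. With full-resolution evaluation the multi-tau
and direct schemes agree to machine precision at shared lags, which the tests
assert at $10^{-10}$ relative.

By default fits are restricted to lags in `[first lag, duration/10]`: on
few-minute traces, the longest-lag estimates are the least sampled and the
most biased.

## The fitter

`fit_acf()` minimizes the (optionally $1/\mathrm{SD}$-weighted) residual sum
of squares with $N$ and all residence times on a log scale and the fractions
as softmax logits, so every iterate satisfies the constraints. Nine starts on
a log-spaced grid of $(\tau_{\mathrm{short}}, \tau_{\mathrm{long}})$ seeds —
$10^{-3}..10^{-1}$ s by $10^{-1}..10^{1}$ s — guard against local minima;
best residual wins, ties break toward the smaller $\tau_{\mathrm{long}}$.
Each start runs BFGS followed by a Nelder–Mead polish (BFGS alone stalls near
machine-zero residuals; the polish brings noiseless round-trips to
$\sim 10^{-11}$ relative error). Binding components are relabeled after
optimization so $\tau_{\mathrm{short}} < \tau_{\mathrm{long}}$ regardless of
initialization. Standard errors come from the Gauss–Newton curvature at the
optimum mapped to the natural scale by the delta method; `bootstrap_se()` is
available when a resampling-based error is preferred.

**A known small-sample property worth stating plainly.** With additive white
noise of SD equal to 5% of the curve amplitude, the free-$\tau_D$ fit of the
full model carries a genuine estimator bias: the diffusion branch and the
short-exponential branch are nearly degenerate at that noise level, and
$f_{\mathrm{long}}$ comes out low by $\approx 0.006$ (with
$\tau_{\mathrm{long}}$ correspondingly high). Dense multi-starts do not
remove it — it is a property of the least-squares functional, not of the
optimizer. Fixing $\tau_D$ at its calibrated value (supported via the
`tau_D` argument, the usual FCS practice of calibrating the observation
volume with a reference of known diffusion) collapses the degeneracy and
makes the recovery unbiased; the parameter-recovery tests use that protocol.

## The trace simulator

`simulate_trace()` integrates point emitters in a periodic box crossed by the
3D Gaussian detection profile. Per time step (equal to the bin width,
default 10 µs): free molecules take Gaussian steps of per-axis variance
$2D\,\Delta t$ and may bind with probability $k_{\mathrm{on}}\Delta t$; bound
molecules are frozen at their capture position (chromatin sites are fixed)
and release with probability $k_{\mathrm{off}}\Delta t$. The configuration is
rejected when any $\mathrm{rate}\times\Delta t > 0.1$, keeping first-order
switching errors below sampling noise. Photon counts per bin are Poisson
draws on $\varepsilon \sum_i W(\mathbf{r}_i) + \mathrm{background}$. Initial
positions are uniform and initial states stationary, so traces start in
steady state. Particle number is $\mathrm{round}(N\,V_{\mathrm{box}}/V_{\mathrm{eff}})$.

The box half-extent is `box_margin` waists per axis ($w_r$ laterally, $w_z$
axially; default 4, detection at the border $< e^{-32}$). The periodic wrap
makes the medium effectively finite: the diffusion ACF is faithful only while
$\sqrt{1+\tau/\tau_D}$ is well below the lateral margin. Studies of the
diffusion tail therefore use wide lateral margins (the recovery tests use
`c(12, 12, 4)`); binding exponentials are unaffected because bound molecules
do not move. Not simulated, matching the model's scope: photobleaching,
triplet blinking, detector afterpulsing, and cell movement.

`generate_acf_curves()` is the fast fixture generator: exact model curves
plus independent per-lag Gaussian noise, on any lag grid. The package uses
its own multi-tau layout spanning $10^{-5}$–$10$ s (143 lags) as the default
grid, i.e. the grid the correlator itself would produce.

## The nucleus generator

`generate_nucleus_image()` voxelizes an ellipsoid (semi-axes in µm),
optionally radially perturbed by the real $Y_{3,2}$ spherical-harmonic
pattern scaled by `deformation_amplitude`, with $2\times2\times2$
partial-volume supersampling; blurs it with a Gaussian PSF (FFT-based,
periodic — objects keep a clear margin); scales to
`background + (peak − background) × occupancy`; and applies Poisson (or
Gaussian) noise. Ground truth volume, surface area and sphericity come from a
dense triangulation of the analytic surface (600 × 1200 parameter grid),
independent of the voxel grid; for spheres and spheroids it reproduces the
closed forms to $\sim 10^{-4}$ relative. What it does not emulate: intensity
inhomogeneity inside the nucleus, neighboring/touching nuclei, depth-dependent
PSF broadening, and anisotropic deformation modes beyond the single harmonic
— so passing tests demonstrate correctness of the measurement chain, not
robustness to every real-microscopy artifact.

## The morphometry chain

1. **Denoise**: 3D median filter (radius 1 voxel) against impulse noise, then
   Rudin–Osher–Fatemi total-variation denoising, $\min_u \|u-f\|^2 +
   2\lambda\,\mathrm{TV}(u)$, solved by Chambolle's dual projection
   (step $1/12$ for 3D, 50 iterations, default weight $0.1\times$ intensity
   range). Edge-preserving smoothing is what makes a global threshold
   reliable.
2. **Segment**: Otsu global threshold (256-bin histogram), 26-connected
   component labeling, slice-wise hole filling, and size gating (defaults
   50–4000 µm³ — generous bounds around ES-cell nuclear volumes). This is a
   deliberately reproducible re-specification of an unspecified commercial
   "automatic surface rendering" step; absolute volumes are comparable only
   within a consistently processed dataset.
3. **Measure**: volume = voxel count × physical voxel volume; surface area
   from a marching-tetrahedra iso-surface at level 0.5 of the binary label,
   meshed in physical coordinates so anisotropic z-spacing is honored without
   resampling. The binary label is pre-smoothed with a 1-voxel Gaussian
   before meshing: iso-surfaces of raw binary masks inherit a lattice
   staircase bias (in the extreme, voxel-face counting overestimates a
   sphere's area by a factor approaching $6/\pi$), while the smoothed
   iso-surface converges to the true area with resolution. Sphericity
   $\Psi = \pi^{1/3}(6V)^{2/3}/A$ may still exceed 1 by a small mesh
   tolerance (0.02) on coarse spheres. Labels touching the image border are
   flagged truncated and excluded from group statistics.

## Group statistics

Groups are summarized as median ± bootstrap SE (morphometry) or mean ±
bootstrap SE (FCS parameters). Two groups are compared with
$z = |m_1 - m_2| / \sqrt{\sigma^2_1+\sigma^2_2}$ and the two-sided normal
p-value $p = 2[1-F(z)]$, where $\sigma^2$ is the **bootstrap variance of the
group statistic** (the statistic being compared is the median or mean, so its
sampling variance is the coherent plug-in; 1000 resamples by default).
Defaults: $\alpha = 0.05$ for morphometry, $0.01$ for FCS comparisons. The
cube-root rule `radius_increment()` converts a volume ratio into the percent
change of the equivalent radius.

Calibration, measured by the package's own tests: with $n = 50$ per group the
empirical type-I error at $\alpha = 0.05$ is ≈ 0.05. With small groups
(e.g. 12 cells) the normal quantile is optimistic — the per-comparison type-I
error at $\alpha = 0.01$ is ≈ 2–3%, so scanning seven parameters flags at
least one in roughly 10–20% of null experiments. That is a property of the
prescribed test, not of the implementation; we report it rather than bolting
on a small-sample correction. Mixed-model/Dunnett analyses are out of scope:
the pipeline exports tidy per-cell tables suitable for external software.

## Pipelines and reproducibility

`run_fcs_pipeline()` (trace or curve per cell → correlate → fit → one row per
cell → group comparisons versus the named control) and
`run_morphometry_pipeline()` (stack → denoise → segment → measure → pooled
per-condition comparisons plus radius increments) never mutate inputs,
exclude unfittable cells and unsegmentable stacks with recorded reasons, and
derive every stage seed from the master seed by hashing (master, stage name,
item index) — reruns are bit-identical, independent of execution order. The
`analysis/` scripts are thin narrative drivers over these functions.

## Problem sizes

The tests and the acceptance script run scaled-down experiments chosen to
keep statistical resolution while staying desk-sized: diffusion-time recovery
uses ten 4-s traces (bin 40 µs, lateral margin 12 waists); residence-time
recovery ten 60-s traces (bin 100 µs, $k_{\mathrm{off}} = 1\,$s⁻¹);
parameter recovery 100 noisy curves on the 143-lag multi-tau grid; power and
null checks 10 repetitions of 12-cell two-condition experiments; morphometry
5 nuclei per condition (radii 3.8–4.2 µm, 0.25 µm voxels) with planted
median-volume ratios $1.06^3$ and $1.03^3$.

## Known limitations

* Absolute characteristic times depend on the optical setup (waists, laser
  power); only within-dataset comparisons are meaningful.
* The free-$\tau_D$ full-model fit is biased at high noise (see above); fix
  $\tau_D$ from calibration when absolute fractions matter.
* The segmentation has no watershed splitting: touching nuclei merge.
* TIFF output quantizes to 16 bits (with the scale recorded in the sidecar).
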