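# fcsmorph

Transcription factors (TFs) such as OCT4 keep embryonic stem cells
pluripotent by binding chromatin, and both their binding dynamics and the
shape of the nucleus respond to cytoskeletal perturbations. `fcsmorph` is an
R package plus analysis workflow for the two quantitative readouts of such
experiments:

1. **Single-point FCS of TF dynamics.** Photon-count traces acquired at one
   nuclear position are autocorrelated and fitted with a diffusion plus
   two-binding-population model to recover the freely diffusing fraction and
   the fractions bound to short- and long-lived chromatin targets, with their
   residence times.
2. **3D nuclear morphometry.** Confocal z-stacks are denoised (median +
   Rudin–Osher–Fatemi total-variation filters), segmented (Otsu threshold,
   26-connected components, hole filling, size gating), and measured:
   per-nucleus volume, iso-surface area, and sphericity, followed by
   bootstrap median comparisons between conditions.

A synthetic-data layer (Brownian-dynamics photon traces with immobile binding
sites, model-exact noisy curves, voxelized nuclei with analytic ground truth)
makes the full chain testable end to end with no external data.

## The model

The autocorrelation of the fluorescence fluctuations is fitted with

```
G(tau) = 1/(2^{3/2} N) * [ f_D * (1 + tau/tau_D)^-1 * (1 + tau/(omega^2 tau_D))^-1/2
                           + f_short * exp(-tau/tau_short)
                           + f_long  * exp(-tau/tau_long) ]
```

with `N` the mean number of molecules in the confocal volume, `tau_D` the
diffusion time, `omega` the axial/radial waist ratio (fixed from
calibration), fractions constrained to `f_D + f_short + f_long = 1`, and
`k_off = 1/tau` for each binding class. Group medians (or means) `m` are
compared with `z = |m1 - m2| / sqrt(s1^2 + s2^2)` using bootstrap variances
`s^2` of the group statistic and the two-sided normal p-value
`p = 2*(1 - F(z))`; volume changes are converted to radius changes by the
cube-root rule `((V_t/V_c)^{1/3} - 1) * 100`.

See `vignettes/fcsmorph-methods.Rmd` for assumptions, conventions, numerical
choices, and known limitations.

## Worked example

Simulate one 30-s photon trace of a TF with two binding classes, correlate,
and fit:

```r
library(fcsmorph)

cfg <- trace_sim_config(
  diffusion_coefficient = 20,          # um^2/s  -> tau_D = 0.78 ms
  N = 2, brightness = 3e4,             # ~21 kHz count rate
  binding_classes = list(c(30, 50),    # k_on, k_off (1/s): tau_short = 20 ms
                         c(0.8, 2)),   #                    tau_long  = 0.5 s
  bin_width = 1e-4, duration = 30, seed = 1)
sim   <- simulate_trace(cfg)
curve <- autocorrelate(sim$trace)       # multi-tau lag layout
fit_acf(curve, omega = 5)
```

```
ACF fit (converged, RSS = 0.002312, 102 lags):
FCS model parameters
  N = 0.7629, omega = 5
  f_D = 0.500 (tau_D = 0.000646 s)
  f_short = 0.333 (tau_short = 0.0205 s)
  f_long = 0.167 (tau_long = 0.205 s)
  k_off_short = 48.67 /s, k_off_long = 4.887 /s
```

The stationary truth of the simulated kinetics is
`f_D/f_short/f_long = 0.50/0.30/0.20`, `tau_short = 20 ms`,
`tau_long = 0.5 s`, and `N = 2/2^{3/2} = 0.71` in the model's amplitude
convention: the fractions, `tau_short`, and `N` come back on target, while a
single 30-s cell constrains `tau_long` only loosely (here 0.2 s) — which is
why the workflow below averages 12 cells per condition before comparing
groups.

Morphometry of a synthetic nucleus:

```r
g   <- generate_nucleus_image(nucleus_shape_spec(
        semi_axes = c(5, 5, 5), psf_sigma = 0.3, voxel_size = rep(0.2, 3)))
rec <- measure(segment_nuclei(denoise(g$image)))
rec[, c("volume_um3", "area_um2", "sphericity")]
#   volume_um3 area_um2 sphericity
# 1    520.912 313.6495  0.9981959     (truth: 523.6, 314.16, 1)
```

## The analysis workflow

Numbered drivers under `analysis/` reproduce a full two-readout study on
synthetic data (a control condition versus an actin-depolymerized-like
condition with enhanced long-lived binding, plus a microtubule-capped-like
condition for morphometry):

```sh
Rscript analysis/01_simulate_fcs.R     # 12 cells/condition -> per-cell ACFs
Rscript analysis/02_fit_fcs.R          # per-cell parameter table
Rscript analysis/03_morphometry.R      # 5 nuclei/condition -> volume/sphericity
Rscript analysis/04_compare_groups.R   # bootstrap comparisons + increments
```

Outputs land under `results/`. In the shipped run, the comparison flags the
planted binding shift and nothing else:

```
FCS comparisons (alpha = 0.01):
     metric       delta        z            p significant
       f_D  0.064251539 3.072282 0.0021242877        TRUE
   f_short  0.060825668 3.824190 0.0001312027        TRUE
    f_long  0.125077207 3.850219 0.0001180121        TRUE
     tau_D  0.001416586 0.513489 0.6076093346       FALSE
  tau_long  0.004088608 0.021672 0.9827098458       FALSE
...
actin_depol: 16.7% median-volume change -> 5.27% radius increment
mt_capped:    8.7% median-volume change -> 2.82% radius increment
```

## Layout

```
R/, src/            package code (R + Rcpp kernels: trace simulator,
                    correlator, 3D image ops, marching-tetrahedra area)
analysis/           numbered workflow drivers
scripts/acceptance.R  from-scratch recomputation of headline numbers
tests/testthat/     unit, property, and end-to-end suites
vignettes/          methods vignette
```
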