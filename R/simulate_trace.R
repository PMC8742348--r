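#' Configuration for the Brownian-dynamics photon-trace simulator
#'
#' Defines a fluorescence fluctuation experiment: molecules diffuse through a
#' periodic box crossed by a 3D Gaussian detection volume (radial waist
#' `w_r`, axial waist `omega * w_r`) and exchange with up to two classes of
#' immobile binding sites via first-order on/off kinetics. `N` is defined
#' over the e^-2 ellipsoidal focal volume `V_eff = pi^{3/2} w_r^2 w_z`; the
#' number of simulated particles is `round(N * V_box / V_eff)`. The box
#' half-extent is `box_margin` waists per axis (`w_r` laterally, `w_z`
#' axially), so detection at the boundary is below `e^{-2 box_margin^2}`.
#'
#' @param diffusion_coefficient D in um^2/s (> 0).
#' @param w_r radial e^-2 waist in um (> 0); default 0.25 um.
#' @param waist_ratio omega = w_z / w_r (> 0); default 5.
#' @param N mean number of molecules in the focal volume (> 0).
#' @param brightness molecular brightness epsilon at beam center, counts/s
#'   per molecule.
#' @param background_rate background count rate, counts/s.
#' @param binding_classes list of up to two `c(k_on, k_off)` pairs (1/s);
#'   ordered short-lived first: `k_off[1] > k_off[2]`.
#' @param bin_width time bin and integration step in s (default 1e-5).
#' @param duration trace length in s (>= 100 bins).
#' @param box_margin box half-extent in waists per axis: scalar or
#'   `c(mx, my, mz)` (default 4). The lateral margin bounds the lag range
#'   over which the diffusion ACF is undistorted by the periodic wrap:
#'   correlations are faithful while `sqrt(1 + tau/tau_D) << mx`, so studies
#'   of the diffusion tail need `mx` well above
#'   `sqrt(1 + tau_max/tau_D)`.
#' @param seed integer seed.
#' @return An object of class `trace_sim_config`.
#' @export
trace_sim_config <- function(diffusion_coefficient, w_r = 0.25,
                             waist_ratio = 5, N = 2, brightness = 3e4,
                             background_rate = 0, binding_classes = list(),
                             bin_width = 1e-5, duration = 10,
                             box_margin = 4, seed = 1L) {
  stopifnot(diffusion_coefficient > 0, w_r > 0, waist_ratio > 0, N > 0,
            brightness >= 0, background_rate >= 0, bin_width > 0,
            length(box_margin) %in% c(1, 3), all(box_margin > 0))
  if (duration < 100 * bin_width)
    stop("duration must be at least 100 bin widths")
  if (length(binding_classes) > 2)
    stop("at most two binding classes are supported")
  for (bc in binding_classes)
    stopifnot(length(bc) == 2, all(bc > 0))
  if (length(binding_classes) == 2 &&
      binding_classes[[1]][2] <= binding_classes[[2]][2])
    stop("classes must be ordered short-lived first (k_off decreasing)")
  rates <- unlist(binding_classes)
  if (length(rates) && max(rates) * bin_width > 0.1)
    stop("rate * bin_width exceeds 0.1; reduce bin_width for accurate kinetics")
  structure(list(diffusion_coefficient = diffusion_coefficient, w_r = w_r,
                 waist_ratio = waist_ratio, N = N, brightness = brightness,
                 background_rate = background_rate,
                 binding_classes = binding_classes, bin_width = bin_width,
                 duration = duration,
                 box_margin = rep_len(as.numeric(box_margin), 3),
                 seed = as.integer(seed)),
            class = "trace_sim_config")
}

#' Ground-truth model parameters implied by a simulator configuration
#'
#' `tau_D = w_r^2 / (4 D)`; residence times are `1/k_off`; stationary bound
#' fractions are `f_j = (k_on_j/k_off_j) / (1 + sum_k k_on_k/k_off_k)`.
#' Absent binding classes get fraction 0 (their residence times are
#' placeholders).
#'
#' The reported `N` is in the model's amplitude convention: the
#' autocorrelation of the simulated trace has zero-lag amplitude
#' `1/(C pi^{3/2} w_r^2 w_z)` exactly, so the `N` that the model (whose
#' prefactor is `1/(2^{3/2} N)`) recovers equals the configured focal-volume
#' occupancy divided by `2^{3/2}` - the 3D-Gaussian shape factor folded into
#' the model amplitude. This keeps simulate -> correlate -> fit a fixed
#' point of the parameter set.
#'
#' @param config a [trace_sim_config].
#' @return An [fcs_params] object.
#' @export
implied_fcs_params <- function(config) {
  stopifnot(inherits(config, "trace_sim_config"))
  tau_D <- config$w_r^2 / (4 * config$diffusion_coefficient)
  ratios <- vapply(config$binding_classes, function(bc) bc[1] / bc[2], 0)
  f_free <- 1 / (1 + sum(ratios))
  f <- ratios * f_free
  nb <- length(config$binding_classes)
  tau_short <- if (nb >= 1) 1 / config$binding_classes[[1]][2] else tau_D * 10
  tau_long <- if (nb >= 2) 1 / config$binding_classes[[2]][2] else
    max(tau_short * 100, 1)
  f_short <- if (nb >= 1) f[1] else 0
  f_long <- if (nb >= 2) f[2] else 0
  # a single binding class is reported as the long-lived component when it is
  # the only one and outlives the diffusion time by orders of magnitude
  if (nb == 1) {
    f_long <- f[1]; f_short <- 0
    tau_long <- 1 / config$binding_classes[[1]][2]
    tau_short <- min(tau_D, tau_long / 100)
  }
  fcs_params(N = config$N / 2^(3 / 2), f_D = f_free, f_short = f_short, f_long = f_long,
             tau_D = tau_D, omega = config$waist_ratio,
             tau_short = tau_short, tau_long = tau_long)
}

#' Simulate a photon-count trace by Brownian dynamics
#'
#' Molecules take Gaussian steps (per-axis variance `2 D dt`) in a periodic
#' box, switch between free and immobile-bound states with first-order
#' probabilities `rate * dt`, and emit photons as Poisson draws with rate
#' `epsilon * sum_i exp(-2(x_i^2+y_i^2)/w_r^2 - 2 z_i^2/w_z^2) + background`.
#' Initial positions are uniform and initial states are drawn from the
#' stationary occupancies, so the trace starts in steady state.
#'
#' @param config a [trace_sim_config].
#' @return List with `trace` (an [intensity_trace]) and `truth`
#'   (the implied [fcs_params], see [implied_fcs_params]).
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "trace_sim_config"))
  w_r <- config$w_r
  w_z <- config$waist_ratio * w_r
  Lx <- 2 * config$box_margin[1] * w_r
  Ly <- 2 * config$box_margin[2] * w_r
  Lz <- 2 * config$box_margin[3] * w_z
  v_box <- Lx * Ly * Lz
  v_eff <- pi^(3 / 2) * w_r^2 * w_z
  if (v_box < v_eff)
    stop("simulation box is smaller than the observation volume")
  n_mol <- round(config$N * v_box / v_eff)
  if (n_mol < 1) stop("configuration implies fewer than one molecule")
  n_bins <- round(config$duration / config$bin_width)
  k_on <- vapply(config$binding_classes, `[`, 0, 1)
  k_off <- vapply(config$binding_classes, `[`, 0, 2)
  counts <- with_seed(config$seed,
    sim_trace_cpp(n_bins, config$bin_width, n_mol,
                  config$diffusion_coefficient, w_r, w_z,
                  config$brightness, config$background_rate,
                  as.numeric(k_on), as.numeric(k_off), Lx, Ly, Lz))
  list(trace = intensity_trace(counts, config$bin_width,
                               label = sprintf("sim_seed%d", config$seed)),
       truth = implied_fcs_params(config))
}

#' Generate noisy model-exact autocorrelation curves
#'
#' Fast fixture generator for the fitter: each curve is the model evaluation
#' ([evaluate_acf_model]) on `lag_grid` plus independent Gaussian noise per
#' lag with standard deviation `noise_sd` (scalar, or a per-lag profile).
#'
#' @param params an [fcs_params] object.
#' @param lag_grid strictly increasing positive lag times (s).
#' @param noise_sd scalar or per-lag vector of noise SDs (>= 0).
#' @param n_curves number of curves.
#' @param seed optional integer seed.
#' @return List of [correlation_curve] objects.
#' @export
generate_acf_curves <- function(params, lag_grid, noise_sd, n_curves,
                                seed = NULL) {
  stopifnot(inherits(params, "fcs_params"), length(lag_grid) > 0,
            all(lag_grid > 0), all(diff(lag_grid) > 0), n_curves >= 1)
  if (any(noise_sd < 0)) stop("noise SD must be non-negative")
  sdv <- rep_len(noise_sd, length(lag_grid))
  g0 <- evaluate_acf_model(params, lag_grid)
  with_seed(seed, lapply(seq_len(n_curves), function(i) {
    correlation_curve(lag_grid, g0 + rnorm(length(lag_grid), 0, sdv))
  }))
}
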