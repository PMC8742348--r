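# shared fixtures: a mixed-population parameter set and its multi-tau lag grid
mix_params <- function() {
  fcs_params(N = 1, f_D = 0.5, f_short = 0.3, f_long = 0.2,
             tau_D = 5e-4, omega = 5, tau_short = 0.02, tau_long = 2)
}

fit_lag_grid <- function(bin = 1e-5, max_s = 10) {
  lags <- multi_tau_lags(round(max_s / bin) * 4) * bin
  lags[lags <= max_s]
}

# direct voxelization of an ellipsoid mask (no PSF, no noise)
ellipsoid_mask <- function(semi_axes, voxel, margin = 1) {
  d <- as.integer(ceiling(2 * (semi_axes + margin) / voxel))
  ctr <- (d + 1) / 2
  x <- ((seq_len(d[1]) - ctr[1]) * voxel[1] / semi_axes[1])^2
  y <- ((seq_len(d[2]) - ctr[2]) * voxel[2] / semi_axes[2])^2
  z <- ((seq_len(d[3]) - ctr[3]) * voxel[3] / semi_axes[3])^2
  inside <- outer(outer(x, y, `+`), z, `+`) <= 1
  nucleus_mask(array(as.integer(inside), d), voxel)
}
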