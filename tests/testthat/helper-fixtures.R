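# Shared acquisition fixtures and simulated-voxel builders.

default_se_spec <- function(alpha_r = 180) echo_train_spec(6.6, 24, alpha_r, 1000)
default_ge_te <- function() exponential_echo_times(2, 1.5, 0.02, 32)$te

# Build a normalized joint voxel from a 14-parameter truth, together with
# the "effective" truth after first-echo normalization (only the pool
# integrals rescale; all shape parameters, MWF, shifts and phase are
# normalization-invariant).
make_joint_voxel <- function(truth, spec = default_se_spec(),
                             te = default_ge_te(), snr = Inf,
                             seed_noise = NULL) {
  m <- do.call(mwi_model, c(list("JOINT"), as.list(truth)))
  grid <- relaxation_grid()
  op <- build_se_operator(grid$t, spec)
  s_se <- se_forward(m, op)
  s_ge <- ge_forward_complex(m, te, grid)
  if (is.finite(snr)) {
    s_se <- Mod(add_complex_noise(s_se, snr, seed = seed_noise))
    s_ge <- add_complex_noise(s_ge, snr,
                              seed = if (is.null(seed_noise)) NULL else seed_noise + 1L)
  }
  eff <- truth
  eff[["i2_t2"]] <- truth[["i2_t2"]] / Mod(s_se[1])
  eff[["i2_t2s"]] <- truth[["i2_t2s"]] / Mod(s_ge[1])
  list(
    voxel = voxel_data(se = normalize_first_echo(s_se), se_spec = spec,
                       ge = normalize_first_echo(s_ge), te_ge = te),
    truth = truth, effective = eff
  )
}

# One uniform draw of a joint truth from the study's simulation ranges
# (shape parameters, shifts, phase), with a phantom-range MWF.
draw_joint_truth <- function() {
  c(mu1_t2 = runif(1, 16, 22), sigma1_t2 = runif(1, 0.2, 1),
    mwf = runif(1, 0.05, 0.3),
    mu2_t2 = runif(1, 65, 80), sigma2_t2 = runif(1, 0.2, 1), i2_t2 = 2,
    mu1_t2s = runif(1, 10, 15), sigma1_t2s = runif(1, 0.2, 1),
    dw1 = runif(1, -10, -2),
    mu2_t2s = runif(1, 48, 62), sigma2_t2s = runif(1, 0.2, 1), i2_t2s = 1,
    dw2 = runif(1, -3, 3), phi0 = runif(1, 0, pi))
}

# Scale a truth's pool integrals so the forward signals have unit
# first-echo magnitude (makes the truth an exact zero of the residual).
unit_first_echo_truth <- function(truth, spec = default_se_spec(),
                                  te = default_ge_te()) {
  m <- do.call(mwi_model, c(list("JOINT"), as.list(truth)))
  grid <- relaxation_grid()
  op <- build_se_operator(grid$t, spec)
  truth[["i2_t2"]] <- truth[["i2_t2"]] / se_forward(m, op)[1]
  truth[["i2_t2s"]] <- truth[["i2_t2s"]] /
    Mod(ge_forward_complex(m, te, grid)[1])
  truth
}
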