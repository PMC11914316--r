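test_that("default configurations carry the reference initial values and bounds", {
  cfg <- default_config("SE", "simulation")
  expect_identical(names(cfg$x_in),
                   c("mu1_t2", "sigma1_t2", "mwf", "mu2_t2", "sigma2_t2", "i2_t2"))
  expect_equal(unname(cfg$x_in), c(18, 0.1, 0.1, 80, 0.1, 2))
  expect_equal(unname(cfg$lower[c("mwf", "mu1_t2", "mu2_t2")]), c(0, 5, 45))
  expect_equal(unname(cfg$upper[c("mwf", "sigma1_t2")]), c(0.85, 5))
  expect_true(all(cfg$lam == 0.01))
  expect_equal(cfg$alpha_se, 2)
  expect_equal(cfg$damping, 0.01)

  cfgj <- default_config("JOINT", "invivo")
  expect_length(cfgj$x_in, 14)
  expect_identical(sum(names(cfgj$x_in) == "mwf"), 1L) # one shared MWF
  expect_equal(unname(cfgj$upper[["phi0"]]), 2 * pi)
  strong <- c("mu1_t2", "mu2_t2", "mu1_t2s", "mu2_t2s", "dw1")
  expect_true(all(cfgj$lam[strong] == 0.02))
  expect_true(all(cfgj$lam[setdiff(names(cfgj$lam), strong)] == 0.01))

  cfgg <- default_config("GE_CPLX", "simulation")
  expect_length(cfgg$x_in, 9)
  expect_equal(unname(cfgg$x_in[c("mu1_t2s", "dw1", "mu2_t2s", "i2_t2s")]),
               c(10, -5, 60, 1))
})

test_that("configurations round-trip through YAML and JSON files", {
  cfg <- default_config("JOINT", "invivo", alpha_se = 3,
                        lam = c(mwf = 0.002), max_iter = 77L)
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_config(cfg, f)
    back <- read_config(f)
    expect_equal(back$x_in, cfg$x_in)
    expect_equal(back$lam, cfg$lam)
    expect_equal(back$alpha_se, 3)
    expect_equal(back$max_iter, 77L)
    expect_equal(back$mode, "JOINT")
  }
})

test_that("the residual vanishes at a truth with unit first echoes", {
  set.seed(31)
  truth <- unit_first_echo_truth(draw_joint_truth())
  mv <- make_joint_voxel(truth)
  cfg <- default_config("JOINT", "simulation",
                        x_in = truth, lam = setNames(rep(0, 14), names(truth)))
  r <- residual_vector(truth, mv$voxel, cfg)
  expect_lt(max(abs(r)), 1e-9)
})

test_that("the stacked residual reproduces the joint objective term by term", {
  set.seed(32)
  truth <- draw_joint_truth()
  mv <- make_joint_voxel(truth, snr = 150, seed_noise = 7L)
  cfg <- default_config("JOINT", "simulation")
  x <- cfg$x_in
  x[["mwf"]] <- 0.2; x[["mu2_t2"]] <- 75
  r <- residual_vector(x, mv$voxel, cfg)

  m <- do.call(mwi_model, c(list("JOINT"), as.list(x)))
  grid <- relaxation_grid()
  op <- build_se_operator(grid$t, mv$voxel$se_spec)
  r_se <- mv$voxel$se - se_forward(m, op)
  r_ge <- mv$voxel$ge - ge_forward_complex(m, mv$voxel$te_ge, grid)
  pen <- cfg$lam * (x - cfg$x_in) / (cfg$upper - cfg$lower)
  expect_equal(sum(r^2),
               2 * sum(r_se^2) + sum(Mod(r_ge)^2) + sum(pen^2),
               tolerance = 1e-10)

  # without regularization, SE mode is the plain data misfit
  cfg_se <- default_config("SE", "simulation",
                           lam = setNames(rep(0, 6), model_par_names("SE")))
  r2 <- residual_vector(x[model_par_names("SE")], mv$voxel, cfg_se)
  expect_equal(sum(r2^2), sum(r_se^2), tolerance = 1e-10)
})

test_that("unnormalized data are rejected", {
  set.seed(33)
  mv <- make_joint_voxel(unit_first_echo_truth(draw_joint_truth()))
  bad <- mv$voxel
  bad$se <- bad$se * 1.3
  cfg <- default_config("JOINT", "simulation")
  expect_error(residual_vector(cfg$x_in, bad, cfg), "normalize")
})

test_that("regularizer rows of the Jacobian are exact and frozen parameters inert", {
  set.seed(34)
  mv <- make_joint_voxel(unit_first_echo_truth(draw_joint_truth()))
  cfg <- default_config("JOINT", "simulation")
  J <- fd_jacobian(cfg$x_in, mv$voxel, cfg)
  np <- length(cfg$x_in)
  lamblock <- J[(nrow(J) - np + 1):nrow(J), ]
  expect_identical(lamblock,
                   diag(unname(cfg$lam / (cfg$upper - cfg$lower))))

  # freeze dw2 with a zero-width interval: its data rows must be zero
  cfg2 <- default_config("JOINT", "simulation",
                         x_in = c(dw2 = 1.5), lower = c(dw2 = 1.5),
                         upper = c(dw2 = 1.5))
  J2 <- fd_jacobian(cfg2$x_in, mv$voxel, cfg2)
  j <- which(names(cfg2$x_in) == "dw2")
  expect_true(all(J2[seq_len(nrow(J2) - np), j] == 0))
})

test_that("finite differences match the analytic derivative of a linear parameter", {
  # with mwf = 0 the SE model is s = i2 * u2, so dr/di2 = -u2 (the decay)
  spec <- default_se_spec(180)
  m <- mwi_model("SE", mu1_t2 = 18, sigma1_t2 = 0.1, mwf = 0,
                 mu2_t2 = 80, sigma2_t2 = 0.1, i2_t2 = 2)
  op <- build_se_operator(relaxation_grid()$t, spec)
  s <- se_forward(m, op)
  vox <- voxel_data(se = s / s[1], se_spec = spec)
  cfg <- default_config("SE", "simulation")
  x <- unclass(m); x[["i2_t2"]] <- 2 / s[1]
  J <- fd_jacobian(x, vox, cfg)
  j <- which(model_par_names("SE") == "i2_t2")
  unit <- mwi_model("SE", mu1_t2 = 18, sigma1_t2 = 0.1, mwf = 0,
                    mu2_t2 = 80, sigma2_t2 = 0.1, i2_t2 = 1)
  expect_equal(J[1:24, j], -se_forward(unit, op), tolerance = 1e-9)
  expect_equal(J[1:24, j], -exp(-spec$te / 80), tolerance = 1e-5)
})

test_that("a perfect initial model is a fixed point of the optimizer", {
  spec <- default_se_spec(170)
  cfg <- default_config("SE", "simulation",
                        lam = setNames(rep(0, 6), model_par_names("SE")))
  # rescale the initial model to unit first echo so it generates the data
  m <- do.call(mwi_model, c(list("SE"), as.list(cfg$x_in)))
  op <- build_se_operator(relaxation_grid()$t, spec)
  s <- se_forward(m, op)
  cfg <- default_config("SE", "simulation",
                        lam = setNames(rep(0, 6), model_par_names("SE")),
                        x_in = c(i2_t2 = 2 / s[1]))
  vox <- voxel_data(se = s / s[1], se_spec = spec)
  fit <- lm_fit(vox, cfg)
  expect_lte(fit$n_iter, 2L)
  expect_lt(fit$cost, 1e-16)
  expect_true(fit$converged)
})

test_that("noise-free joint data from a known truth recover the MWF", {
  truth <- c(mu1_t2 = 20, sigma1_t2 = 0.5, mwf = 0.15, mu2_t2 = 70,
             sigma2_t2 = 0.5, i2_t2 = 2, mu1_t2s = 12, sigma1_t2s = 0.5,
             dw1 = -6, mu2_t2s = 55, sigma2_t2s = 0.5, i2_t2s = 1,
             dw2 = 1, phi0 = 0.5)
  mv <- make_joint_voxel(truth)
  fit <- lm_fit(mv$voxel, default_config("JOINT", "simulation"))
  expect_lt(abs(fit$x_hat[["mwf"]] - 0.15), 0.005)
  for (p in c("mu1_t2", "mu2_t2", "mu1_t2s", "mu2_t2s"))
    expect_lt(abs(fit$x_hat[[p]] - truth[[p]]), 1)
})

test_that("median noise-free MWF recovery error stays below 0.005", {
  set.seed(55)
  errs <- replicate(6, {
    truth <- draw_joint_truth()
    mv <- make_joint_voxel(truth)
    fit <- lm_fit(mv$voxel, default_config("JOINT", "simulation"))
    abs(fit$x_hat[["mwf"]] - truth[["mwf"]])
  })
  expect_lt(median(errs), 0.005)
})

test_that("bounds are respected and a zero-MWF truth is recovered at the bound", {
  spec <- default_se_spec(180)
  m <- mwi_model("SE", mu1_t2 = 18, sigma1_t2 = 0.3, mwf = 0,
                 mu2_t2 = 72, sigma2_t2 = 0.3, i2_t2 = 2)
  op <- build_se_operator(relaxation_grid()$t, spec)
  s <- se_forward(m, op)
  vox <- voxel_data(se = s / s[1], se_spec = spec)
  cfg <- default_config("SE", "simulation")
  fit <- lm_fit(vox, cfg)
  expect_gte(fit$x_hat[["mwf"]], 0)
  expect_lte(fit$x_hat[["mwf"]], 0.01)
  expect_true(all(unclass(fit$x_hat) >= cfg$lower - 1e-12))
  expect_true(all(unclass(fit$x_hat) <= cfg$upper + 1e-12))
})

test_that("the optimizer is monotone in cost and fully deterministic", {
  set.seed(36)
  truth <- draw_joint_truth()
  mv <- make_joint_voxel(truth, snr = 150, seed_noise = 9L)
  cfg <- default_config("JOINT", "simulation", phi0_init = "fixed")
  fit1 <- lm_fit(mv$voxel, cfg)
  fit2 <- lm_fit(mv$voxel, cfg)
  expect_identical(fit1, fit2)
  r0 <- residual_vector(cfg$x_in, mv$voxel, cfg)
  expect_lte(fit1$cost, sum(r0^2))
  # every returned parameter feasible
  expect_true(all(unclass(fit1$x_hat) >= cfg$lower &
                  unclass(fit1$x_hat) <= cfg$upper))
})

test_that("degenerate voxels short-circuit with the initial model", {
  spec <- default_se_spec()
  cfg <- default_config("SE", "simulation")
  z <- voxel_data(se = rep(0, 24), se_spec = spec)
  fit <- lm_fit(z, cfg)
  expect_identical(fit$status, "degenerate_input")
  expect_false(fit$converged)
  expect_equal(as.numeric(fit$x_hat), unname(cfg$x_in))
  nf <- voxel_data(se = c(NA, rep(0.5, 23)), se_spec = spec)
  expect_identical(lm_fit(nf, cfg)$status, "degenerate_input")
})

test_that("regularization pulls estimates towards the initial model", {
  # on pure-noise data (no decay structure the model could prefer), the
  # distance of the estimate from x_in must shrink as lambda grows, and a
  # dominant penalty pins the estimate at x_in
  set.seed(37)
  spec <- default_se_spec()
  noise <- abs(rnorm(24, 0, 1 / 150))
  noise[1] <- 1
  vox <- voxel_data(se = noise, se_spec = spec)
  pars <- model_par_names("SE")
  dist_to_xin <- function(lam_value) {
    cfg <- default_config("SE", "simulation",
                          lam = setNames(rep(lam_value, 6), pars))
    fit <- lm_fit(vox, cfg)
    w <- cfg$upper - cfg$lower
    sqrt(sum(((unclass(fit$x_hat) - cfg$x_in) / w)^2))
  }
  d <- vapply(c(0, 0.05, 5, 500), dist_to_xin, numeric(1))
  expect_true(all(diff(d) <= 1e-9)) # monotone pull
  expect_lt(d[4], 1e-3) # dominant penalty pins the initial model
})
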