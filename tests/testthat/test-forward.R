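test_that("discretized spectra conserve compartment masses exactly", {
  grid <- relaxation_grid()
  set.seed(4)
  for (rep in 1:25) {
    mu1 <- runif(1, 5, 35); sg1 <- runif(1, 0.1, 5)
    mu2 <- runif(1, 45, 180); sg2 <- runif(1, 0.1, 5)
    mwf <- runif(1, 0, 0.8); i2 <- runif(1, 0.1, 5)
    i1 <- myelin_integral(mwf, i2)
    sp <- discretize_bigaussian(mu1, sg1, i1, mu2, sg2, i2, grid)
    expect_lt(abs(sum(sp$weights[1, ]) - i1), 1e-12 * max(1, i1))
    expect_lt(abs(sum(sp$weights[2, ]) - i2), 1e-12 * i2)
  }
})

test_that("myelin integral follows from the MWF definition", {
  expect_equal(myelin_integral(0.1, 2), 2 * 0.1 / 0.9)
  sp <- discretize_bigaussian(18, 0.5, myelin_integral(0.1, 2), 80, 0.5, 2,
                              relaxation_grid())
  expect_equal(sum(sp$weights), 2 + 2 * 0.1 / 0.9, tolerance = 1e-12)
  # mwf = 0: the myelin compartment carries no mass at all
  sp0 <- discretize_bigaussian(18, 0.5, myelin_integral(0, 2), 80, 0.5, 2,
                               relaxation_grid())
  expect_identical(sp0$weights[1, ], rep(0, length(sp0$grid)))
})

test_that("a very narrow Gaussian lands, with full mass, at its mean's grid cell", {
  grid <- relaxation_grid()
  sp <- discretize_bigaussian(18, 0.1, 0.3, 80, 0.1, 2, grid)
  expect_equal(sum(sp$weights[1, ]), 0.3, tolerance = 1e-12)
  # all mass lands on the few nodes around 18 ms
  near <- abs(sp$grid - 18) < 5 * 18 * diff(log(range(grid$t))) / length(grid$t)
  expect_equal(sum(sp$weights[1, near]), 0.3, tolerance = 1e-9)
})

test_that("means outside the grid support warn and clip into boundary cells", {
  grid <- relaxation_grid(100, c(5, 200))
  expect_warning(sp <- discretize_bigaussian(1, 0.2, 1, 80, 0.5, 2, grid),
                 "clipped")
  expect_equal(sum(sp$weights[1, ]), 1, tolerance = 1e-12)
  expect_gt(sp$weights[1, 1], 0.9)
})

test_that("delta-like spectrum at 180 degrees gives mono-exponential SE decay", {
  spec <- default_se_spec(180)
  op <- build_se_operator(relaxation_grid()$t, spec)
  m <- mwi_model("SE", mu1_t2 = 18, sigma1_t2 = 0.1, mwf = 0,
                 mu2_t2 = 80, sigma2_t2 = 0.1, i2_t2 = 1)
  expect_lt(max(abs(se_forward(m, op) - exp(-spec$te / 80))), 1e-6)
})

test_that("SE forward matches EPG-kernel quadrature for two-pool spectra", {
  spec <- default_se_spec(150)
  op <- build_se_operator(relaxation_grid()$t, spec)
  set.seed(9)
  for (rep in 1:5) {
    mu1 <- runif(1, 10, 30); sg1 <- runif(1, 0.2, 3)
    mu2 <- runif(1, 50, 120); sg2 <- runif(1, 0.2, 3)
    mwf <- runif(1, 0.05, 0.4); i2 <- runif(1, 0.5, 3)
    m <- mwi_model("SE", mu1_t2 = mu1, sigma1_t2 = sg1, mwf = mwf,
                   mu2_t2 = mu2, sigma2_t2 = sg2, i2_t2 = i2)
    s <- se_forward(m, op)
    oracle <- quad_gauss_epg(spec, mu1, sg1, myelin_integral(mwf, i2)) +
      quad_gauss_epg(spec, mu2, sg2, i2)
    expect_lt(max(abs(s - oracle)) / max(oracle), 1e-4)
  }
})

test_that("SE forward at 180 degrees matches the two-exponential closed form", {
  spec <- default_se_spec(180)
  op <- build_se_operator(relaxation_grid()$t, spec)
  m <- mwi_model("SE", mu1_t2 = 20, sigma1_t2 = 0.1, mwf = 0.2,
                 mu2_t2 = 80, sigma2_t2 = 0.1, i2_t2 = 2)
  i1 <- myelin_integral(0.2, 2)
  closed <- i1 * exp(-spec$te / 20) + 2 * exp(-spec$te / 80)
  expect_lt(max(abs(se_forward(m, op) - closed)) / max(closed), 1e-4)
})

test_that("forward signals are linear in the pool integrals", {
  spec <- default_se_spec(160)
  op <- build_se_operator(relaxation_grid()$t, spec)
  m1 <- mwi_model("SE", mu1_t2 = 20, sigma1_t2 = 0.5, mwf = 0.15,
                  mu2_t2 = 70, sigma2_t2 = 0.5, i2_t2 = 1.5)
  m2 <- mwi_model("SE", mu1_t2 = 20, sigma1_t2 = 0.5, mwf = 0.15,
                  mu2_t2 = 70, sigma2_t2 = 0.5, i2_t2 = 3)
  expect_equal(se_forward(m2, op), 2 * se_forward(m1, op), tolerance = 1e-12)
})

test_that("complex GE forward matches the quadrature oracle", {
  te <- default_ge_te()
  # the spec-style spot check at three echo times
  m <- mwi_model("GE_CPLX", mu1_t2s = 10, sigma1_t2s = 0.5, dw1 = -6,
                 mwf = 0.2, mu2_t2s = 60, sigma2_t2s = 0.5, i2_t2s = 1,
                 dw2 = 0, phi0 = 0.3)
  te3 <- c(2, 10, 30)
  s <- ge_forward_complex(m, te3)
  oracle <- quad_ge_complex(m, te3)
  expect_lt(max(Mod(s - oracle) / Mod(oracle)), 1e-4)
  # random feasible models over the full schedule
  set.seed(21)
  for (rep in 1:5) {
    mm <- mwi_model("GE_CPLX",
                    mu1_t2s = runif(1, 5, 25), sigma1_t2s = runif(1, 0.1, 5),
                    dw1 = runif(1, -75, 75), mwf = runif(1, 0, 0.8),
                    mu2_t2s = runif(1, 45, 180), sigma2_t2s = runif(1, 0.1, 5),
                    i2_t2s = runif(1, 0.1, 5), dw2 = runif(1, -75, 75),
                    phi0 = runif(1, 0, 2 * pi))
    s <- ge_forward_complex(mm, te)
    oracle <- quad_ge_complex(mm, te)
    expect_lt(max(Mod(s - oracle)) / max(Mod(oracle)), 1e-4)
  }
})

test_that("phase-free complex GE equals the magnitude forward and is real", {
  te <- default_ge_te()
  mc <- mwi_model("GE_CPLX", mu1_t2s = 12, sigma1_t2s = 0.6, dw1 = 0,
                  mwf = 0.18, mu2_t2s = 58, sigma2_t2s = 0.7, i2_t2s = 1,
                  dw2 = 0, phi0 = 0)
  mm <- mwi_model("GE_MAG", mu1_t2s = 12, sigma1_t2s = 0.6, mwf = 0.18,
                  mu2_t2s = 58, sigma2_t2s = 0.7, i2_t2s = 1)
  sc <- ge_forward_complex(mc, te)
  expect_lt(max(abs(Im(sc))), 1e-14)
  expect_equal(Re(sc), ge_forward_magnitude(mm, te), tolerance = 1e-12)
})

test_that("the signal at t = 0 carries the total spectral mass", {
  m <- mwi_model("GE_CPLX", mu1_t2s = 12, sigma1_t2s = 0.6, dw1 = -6,
                 mwf = 0.2, mu2_t2s = 58, sigma2_t2s = 0.7, i2_t2s = 1,
                 dw2 = 1, phi0 = 0.4)
  s0 <- ge_forward_complex(m, c(1e-9, 2))
  expect_equal(Mod(s0[1]), 1 + myelin_integral(0.2, 1), tolerance = 1e-6)
})

test_that("a global phase offset rotates all echoes identically", {
  te <- default_ge_te()
  base <- list(mu1_t2s = 12, sigma1_t2s = 0.6, dw1 = -6, mwf = 0.2,
               mu2_t2s = 58, sigma2_t2s = 0.7, i2_t2s = 1, dw2 = 1)
  m0 <- do.call(mwi_model, c(list("GE_CPLX"), base, phi0 = 0))
  m1 <- do.call(mwi_model, c(list("GE_CPLX"), base, phi0 = 1.1))
  expect_equal(ge_forward_complex(m1, te),
               ge_forward_complex(m0, te) * exp(1.1i), tolerance = 1e-12)
})

test_that("forward signals converge under grid refinement", {
  te <- default_ge_te()
  set.seed(14)
  g200 <- relaxation_grid()
  g800 <- relaxation_grid(900)
  for (rep in 1:5) {
    m <- mwi_model("GE_CPLX",
                   mu1_t2s = runif(1, 5, 25), sigma1_t2s = runif(1, 0.1, 5),
                   dw1 = runif(1, -75, 75), mwf = runif(1, 0, 0.8),
                   mu2_t2s = runif(1, 45, 180), sigma2_t2s = runif(1, 0.1, 5),
                   i2_t2s = runif(1, 0.1, 5), dw2 = runif(1, -75, 75),
                   phi0 = runif(1, 0, 2 * pi))
    a <- ge_forward_complex(m, te, g200)
    b <- ge_forward_complex(m, te, g800)
    expect_lt(max(Mod(a - b)) / max(Mod(b)), 1e-5)
  }
})

test_that("forward evaluations are deterministic and pure", {
  te <- default_ge_te()
  m <- mwi_model("GE_CPLX", mu1_t2s = 12, sigma1_t2s = 0.6, dw1 = -6,
                 mwf = 0.2, mu2_t2s = 58, sigma2_t2s = 0.7, i2_t2s = 1,
                 dw2 = 1, phi0 = 0.4)
  expect_identical(ge_forward_complex(m, te), ge_forward_complex(m, te))
  spec <- default_se_spec(150)
  op <- build_se_operator(relaxation_grid()$t, spec)
  ms <- mwi_model("SE", mu1_t2 = 20, sigma1_t2 = 0.5, mwf = 0.15,
                  mu2_t2 = 70, sigma2_t2 = 0.5, i2_t2 = 2)
  expect_identical(se_forward(ms, op), se_forward(ms, op))
})

test_that("model construction enforces mode fields and MWF range", {
  expect_error(mwi_model("SE", mu1_t2 = 18), "needs exactly")
  expect_error(mwi_model("SE", mu1_t2 = 18, sigma1_t2 = 0.1, mwf = 0.9,
                         mu2_t2 = 80, sigma2_t2 = 0.1, i2_t2 = 2),
               "mwf")
  expect_length(model_par_names("JOINT"), 14)
  expect_length(model_par_names("GE_CPLX"), 9)
})
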