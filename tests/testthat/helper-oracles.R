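# Independent numerical oracles used across the tests. These deliberately
# avoid the package's EPG / operator code paths.

# Brute-force isochromat Bloch simulation of a CPMG train: n_spins
# uniformly dephased isochromats, hard-pulse rotations, exponential
# relaxation with T1 regrowth, ideal crushers realised as one net
# dephasing increment per half echo spacing.
isochromat_cpmg <- function(t2, spec, n_spins = 10000L) {
  th <- 2 * pi * (seq_len(n_spins) - 0.5) / n_spins
  e2 <- exp(-spec$echo_spacing / 2 / t2)
  e1 <- exp(-spec$echo_spacing / 2 / spec$t1)
  rot <- function(M, a, phi) {
    # rotation by angle a about the in-plane axis at azimuth phi
    ca <- cos(a); sa <- sin(a); cp <- cos(phi); sp <- sin(phi)
    x <- M[, 1]; y <- M[, 2]; z <- M[, 3]
    x1 <- cp * x + sp * y; y1 <- -sp * x + cp * y
    y2 <- ca * y1 + sa * z; z2 <- -sa * y1 + ca * z
    cbind(cp * x1 - sp * y2, sp * x1 + cp * y2, z2)
  }
  half <- function(M) {
    x <- M[, 1] * e2; y <- M[, 2] * e2
    z <- 1 + (M[, 3] - 1) * e1
    cbind(cos(th) * x - sin(th) * y, sin(th) * x + cos(th) * y, z)
  }
  M <- cbind(rep(0, n_spins), rep(0, n_spins), rep(1, n_spins))
  M <- rot(M, pi / 2, pi / 2) # excitation, CPMG condition
  out <- numeric(spec$etl)
  for (k in seq_len(spec$etl)) {
    M <- half(M)
    M <- rot(M, spec$alpha_r * pi / 180, 0)
    M <- half(M)
    out[k] <- Mod(mean(complex(real = M[, 1], imaginary = M[, 2])))
  }
  out
}

# Adaptive quadrature of one Gaussian compartment against the
# mono-exponential decay kernel: integral of I * N(mu, sigma) * exp(-t/T)
# over T in (0, mu + 13 sigma).
quad_gauss_exp <- function(te, mu, sigma, i) {
  vapply(te, function(t) {
    stats::integrate(function(T2) i * stats::dnorm(T2, mu, sigma) * exp(-t / T2),
                     1e-12, mu + 13 * sigma, rel.tol = 1e-12,
                     subdivisions = 400L)$value
  }, numeric(1))
}

# Quadrature of one Gaussian compartment against the EPG kernel:
# Gauss-Legendre on mu +- 10 sigma, with node doubling until converged.
quad_gauss_epg <- function(spec, mu, sigma, i, tol = 1e-8) {
  eval_n <- function(n) {
    gl <- pracma::gaussLegendre(n, -10, 10)
    nodes <- pmax(mu + sigma * gl$x, 1e-9)
    K <- vapply(nodes, function(T2) epg_cpmg_signal(T2, spec),
                numeric(spec$etl))
    as.vector(K %*% (gl$w * stats::dnorm(gl$x) * i))
  }
  n <- 48L
  prev <- eval_n(n)
  repeat {
    n <- 2L * n
    cur <- eval_n(n)
    if (max(abs(cur - prev)) < tol || n >= 384L) return(cur)
    prev <- cur
  }
}

# Complex GE signal oracle for a full two-pool model (list or named vector
# with T2* fields), via adaptive quadrature plus analytic phase factors.
quad_ge_complex <- function(x, te) {
  x <- as.list(x)
  i1 <- x$i2_t2s * x$mwf / (1 - x$mwf)
  q1 <- quad_gauss_exp(te, x$mu1_t2s, x$sigma1_t2s, i1)
  q2 <- quad_gauss_exp(te, x$mu2_t2s, x$sigma2_t2s, x$i2_t2s)
  tw <- 2e-3 * pi * te
  (q1 * exp(1i * x$dw1 * tw) + q2 * exp(1i * x$dw2 * tw)) * exp(1i * x$phi0)
}
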