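#' Procedural myelin-water-fraction phantom
#'
#' Deterministic (seeded) 2-D phantom map of MWF values: piecewise-constant
#' rectangular "white-matter-like" regions with MWF levels in
#' \[0.05, 0.30\] on a zero background. Background voxels (MWF = 0) are
#' flagged and excluded from fitting, mimicking the discontinuous value
#' range of an atlas slice. A pre-computed MWF map (e.g. read from NIfTI)
#' can be passed through with `style = "from_file"`.
#'
#' @param shape Length-2 integer vector (rows, columns), each >= 8.
#' @param style `"blocks"` (default), `"smooth"`, or `"from_file"`.
#' @param seed Integer seed controlling the layout (ignored for
#'   `from_file`).
#' @param n_regions Number of distinct nonzero MWF regions (blocks style).
#' @param values For `style = "from_file"`: a numeric matrix/array of MWF
#'   fractions in \[0, 0.85).
#' @return Object of class `mwi_phantom`: list with `mwf` (matrix), `mask`
#'   (logical matrix, TRUE where fitted), `style`, `seed`.
#' @export
make_phantom <- function(shape = c(32, 32), style = c("blocks", "smooth", "from_file"),
                         seed = 1L, n_regions = 6L, values = NULL) {
  style <- match.arg(style)
  if (style == "from_file") {
    stopifnot(!is.null(values))
    v <- as.matrix(values)
    if (any(!is.finite(v)) || any(v < 0) || any(v >= 0.85))
      abort("from_file phantom values must be finite MWF fractions in [0, 0.85)")
    return(structure(list(mwf = v, mask = v > 0, style = style, seed = NA_integer_),
                     class = "mwi_phantom"))
  }
  stopifnot(length(shape) == 2, all(shape >= 8))
  nr <- shape[1]; nc <- shape[2]
  mwf <- withr::with_seed(as.integer(seed), {
    m <- matrix(0, nr, nc)
    if (style == "blocks") {
      levels <- runif(n_regions, 0.05, 0.30)
      # lay regions on a jittered coarse lattice so every level stays visible
      k <- ceiling(sqrt(n_regions))
      cells <- sample(k * k, n_regions)
      for (q in seq_len(n_regions)) {
        ci <- (cells[q] - 1) %% k
        cj <- (cells[q] - 1) %/% k
        r0 <- floor(ci * nr / k) + 1L; r1 <- floor((ci + 1) * nr / k)
        c0 <- floor(cj * nc / k) + 1L; c1 <- floor((cj + 1) * nc / k)
        # random sub-rectangle of the lattice cell, at least 2x2
        rr <- sort(sample(r0:r1, 2)); cc <- sort(sample(c0:c1, 2))
        rr[2] <- max(rr[2], min(rr[1] + 1L, r1))
        cc[2] <- max(cc[2], min(cc[1] + 1L, c1))
        m[rr[1]:rr[2], cc[1]:cc[2]] <- levels[q]
      }
    } else { # smooth
      f <- function(n) {
        x <- seq(0, 1, length.out = n)
        a <- rnorm(4)
        a[1] * sin(2 * pi * x) + a[2] * cos(2 * pi * x) +
          a[3] * sin(4 * pi * x) + a[4] * cos(4 * pi * x)
      }
      s <- outer(f(nr), f(nc)) + outer(f(nr), f(nc))
      s <- (s - min(s)) / (max(s) - min(s))
      m <- matrix(0.05 + 0.25 * s, nr, nc)
      # zero background frame so background flagging has something to flag
      m[c(1, nr), ] <- 0; m[, c(1, nc)] <- 0
    }
    m
  })
  structure(list(mwf = mwf, mask = mwf > 0, style = style, seed = as.integer(seed)),
            class = "mwi_phantom")
}

#' Draw one simulation run's spectrum parameters
#'
#' Uniform draws of the two-pool Gaussian shape parameters, compartmental
#' frequency shifts and constant phase within the study's ranges:
#' mu1_T2 in \[16, 22\] ms, mu2_T2 in \[65, 80\] ms, mu1_T2* in \[10, 15\] ms,
#' mu2_T2* in \[48, 62\] ms, all sigmas in \[0.2, 1\] ms, dw1 in
#' \[-10, -2\] Hz, dw2 in \[-3, 3\] Hz, phi0 in \[0, pi\] rad. The ranges
#' guarantee T2* <= T2 for the paired pools. Pool integrals are held at
#' the constants i2_t2 = 2 and i2_t2s = 1; per-voxel integrals are later
#' rescaled so the myelin/total ratio matches the phantom MWF.
#'
#' @param seed Integer seed; draws are deterministic per seed.
#' @return A one-row tibble of class `mwi_run_params` with the parameter
#'   columns and the seed.
#' @export
draw_run_parameters <- function(seed = 1L) {
  p <- withr::with_seed(as.integer(seed), tibble(
    mu1_t2 = runif(1, 16, 22),
    mu2_t2 = runif(1, 65, 80),
    mu1_t2s = runif(1, 10, 15),
    mu2_t2s = runif(1, 48, 62),
    sigma1_t2 = runif(1, 0.2, 1),
    sigma2_t2 = runif(1, 0.2, 1),
    sigma1_t2s = runif(1, 0.2, 1),
    sigma2_t2s = runif(1, 0.2, 1),
    dw1 = runif(1, -10, -2),
    dw2 = runif(1, -3, 3),
    phi0 = runif(1, 0, pi),
    i2_t2 = 2,
    i2_t2s = 1,
    seed = as.integer(seed)
  ))
  class(p) <- c("mwi_run_params", class(p))
  p
}

#' Add complex Gaussian noise at a first-echo SNR
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation
#' `|S(TE_first)| / snr` independently to the real and imaginary channels
#' of each voxel's signal. Magnitude (Rician) SE data are formed by the
#' caller by taking `Mod()` afterwards; GE data stay complex.
#'
#' @param signal Complex (or real) vector, or an array whose last
#'   dimension indexes echoes.
#' @param snr First-echo signal-to-noise ratio (> 0); `Inf` disables noise.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Complex object of the same shape.
#' @export
add_complex_noise <- function(signal, snr, seed = NULL) {
  stopifnot(is.numeric(snr) || is.infinite(snr), length(snr) == 1, snr > 0)
  x <- if (is.complex(signal)) signal else {
    xc <- complex(real = signal, imaginary = 0)
    dim(xc) <- dim(signal)
    xc
  }
  if (is.infinite(snr)) return(x)
  addn <- function() {
    d <- dim(x)
    if (is.null(d)) {
      sig <- Mod(x[1]) / snr
      x + complex(real = rnorm(length(x), 0, sig),
                  imaginary = rnorm(length(x), 0, sig))
    } else {
      ne <- d[length(d)]
      nv <- prod(d[-length(d)])
      m <- matrix(x, nv, ne)
      sig <- Mod(m[, 1]) / snr # per-voxel first-echo noise level
      out <- m + complex(real = rnorm(nv * ne, 0, sig),
                         imaginary = rnorm(nv * ne, 0, sig))
      array(out, d)
    }
  }
  if (is.null(seed)) addn() else withr::with_seed(as.integer(seed), addn())
}

#' Simulate a paired ME-SE / ME-GE dataset from a phantom
#'
#' For every phantom voxel, builds the two-pool T2 and T2* spectra from the
#' run's shape parameters with the pool integrals scaled so the
#' myelin/total ratio equals the voxel's MWF, evaluates the EPG spin-echo
#' and complex gradient-echo forward models, and adds complex Gaussian
#' noise (SE volumes are Rician magnitudes, GE volumes stay complex).
#' Because the run parameters are shared across voxels, signals depend on
#' the voxel only through its MWF, so the volume is synthesized from
#' per-compartment unit signals in closed form.
#'
#' @param phantom [make_phantom()] result (or an `mwi_phantom`).
#' @param run [draw_run_parameters()] row.
#' @param se_spec [echo_train_spec()]; default mirrors the in-vivo
#'   protocol (6.6 ms spacing, 24 echoes, nominal 180 degrees).
#' @param ge_te [exponential_echo_times()] schedule or echo-time vector;
#'   default (2, 1.5, 0.02, 32).
#' @param snr First-echo SNR of the added complex noise (default 150);
#'   `Inf` for noise-free data.
#' @param seed_noise Integer seed for the noise draws.
#' @param grid Relaxation grid used by the forward models.
#' @return Object of class `mwi_dataset`: list with `se` (array
#'   rows x cols x etl), `ge` (complex array rows x cols x n_ge), `phantom`,
#'   `run`, `se_spec`, `ge_te`, `snr`, `seed_noise`.
#' @export
simulate_dataset <- function(phantom, run,
                             se_spec = echo_train_spec(6.6, 24, 180),
                             ge_te = exponential_echo_times(2, 1.5, 0.02, 32),
                             snr = 150, seed_noise = 1L,
                             grid = relaxation_grid()) {
  stopifnot(inherits(phantom, "mwi_phantom"), inherits(run, "mwi_run_params"))
  te <- echo_times(ge_te)
  grid <- as_mwi_grid(grid)
  r <- as.list(run[1, ])
  A_se <- build_se_operator(grid$t, se_spec)$matrix
  A_ge <- build_ge_operator(te, grid)$matrix
  u_se1 <- as.vector(A_se %*% discretize_gaussian(r$mu1_t2, r$sigma1_t2, 1, grid))
  u_se2 <- as.vector(A_se %*% discretize_gaussian(r$mu2_t2, r$sigma2_t2, 1, grid))
  u_ge1 <- as.vector(A_ge %*% discretize_gaussian(r$mu1_t2s, r$sigma1_t2s, 1, grid))
  u_ge2 <- as.vector(A_ge %*% discretize_gaussian(r$mu2_t2s, r$sigma2_t2s, 1, grid))
  tw <- 2e-3 * pi * te
  ph1 <- exp(1i * (r$dw1 * tw + r$phi0))
  ph2 <- exp(1i * (r$dw2 * tw + r$phi0))
  mwf <- phantom$mwf
  c1 <- mwf / (1 - mwf) # I1 = I2 * mwf / (1 - mwf)
  nv <- length(mwf)
  # voxel-major outer products: volume = I1(v) * u1 + I2 * u2
  se <- outer(as.vector(c1) * r$i2_t2, u_se1) + outer(rep(r$i2_t2, nv), u_se2)
  ge <- outer(as.vector(c1) * r$i2_t2s, u_ge1 * ph1) +
        outer(rep(r$i2_t2s, nv), u_ge2 * ph2)
  dim(se) <- c(dim(mwf), length(u_se1))
  dim(ge) <- c(dim(mwf), length(te))
  se_noisy <- Mod(add_complex_noise(se, snr, seed = seed_noise))
  ge_noisy <- add_complex_noise(ge, snr, seed = as.integer(seed_noise) + 1L)
  structure(list(se = se_noisy, ge = ge_noisy, phantom = phantom, run = run,
                 se_spec = se_spec, ge_te = ge_te, snr = snr,
                 seed_noise = as.integer(seed_noise)),
            class = "mwi_dataset")
}
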