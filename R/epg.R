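#' CPMG echo-train description
#'
#' Bundles the parameters that determine the spin-echo forward kernel: the
#' CPMG echo spacing, echo-train length, effective refocusing flip angle
#' (nominal angle times relative B1) and the longitudinal relaxation time
#' used in the extended-phase-graph (EPG) simulation. The first echo forms
#' at one echo spacing; echo k at `k * echo_spacing`.
#'
#' T1 defaults to 1000 ms: for brain tissue T1 >> T2 and the echo
#' amplitudes depend only weakly on T1, so a fixed approximate value is
#' sufficient.
#'
#' @param echo_spacing CPMG echo spacing in ms (> 0).
#' @param etl Echo-train length, i.e. number of echoes (>= 1).
#' @param alpha_r Refocusing flip angle in degrees, in (0, 180].
#' @param t1 Longitudinal relaxation time in ms (> 0).
#'
#' @return An object of class `mwi_echo_train`: list with the validated
#'   fields plus `te`, the echo-time vector `k * echo_spacing` (ms).
#' @examples
#' echo_train_spec(6.6, 24, 180)
#' @export
echo_train_spec <- function(echo_spacing, etl, alpha_r = 180, t1 = 1000) {
  stopifnot(is.numeric(echo_spacing), length(echo_spacing) == 1, echo_spacing > 0,
            is.numeric(etl), length(etl) == 1, etl >= 1,
            is.numeric(alpha_r), length(alpha_r) == 1,
            alpha_r > 0, alpha_r <= 180,
            is.numeric(t1), length(t1) == 1, t1 > 0)
  etl <- as.integer(etl)
  structure(
    list(echo_spacing = echo_spacing, etl = etl, alpha_r = alpha_r, t1 = t1,
         te = echo_spacing * seq_len(etl)),
    class = "mwi_echo_train"
  )
}

# EPG RF mixing matrix for flip angle `a` (rad) and pulse phase `phi` (rad),
# acting on the state rows (F+, F-, Z). Standard complex convention; only
# echo magnitudes are consumed downstream.
epg_rf_matrix <- function(a, phi) {
  ca2 <- cos(a / 2)^2
  sa2 <- sin(a / 2)^2
  sa <- sin(a)
  matrix(c(
    ca2,                          exp(2i * phi) * sa2,      -1i * exp(1i * phi) * sa,
    exp(-2i * phi) * sa2,         ca2,                       1i * exp(-1i * phi) * sa,
    -0.5i * exp(-1i * phi) * sa,  0.5i * exp(1i * phi) * sa, cos(a) + 0i
  ), nrow = 3, byrow = TRUE)
}

#' EPG echo amplitudes of a CPMG train
#'
#' Simulates the transverse magnitude at each echo of a CPMG spin-echo train
#' for a single T2 species with the extended phase graph algorithm: ideal
#' 90 degree excitation (phase 90 degrees off the refocusing pulses, i.e.
#' the CPMG condition), hard refocusing pulses at `spec$alpha_r`,
#' T1/T2 relaxation over each half echo spacing, and ideal crusher
#' dephasing expressed by the EPG configuration-order shift. All etl + 1
#' configuration orders are retained, so there is no truncation error.
#'
#' At `alpha_r = 180` all stimulated-echo pathways vanish and the
#' amplitudes reduce to `exp(-te / t2)`.
#'
#' @param t2 Transverse relaxation time in ms (> 0).
#' @param spec An [echo_train_spec()].
#' @return Numeric vector of `spec$etl` echo amplitudes for unit initial
#'   magnetization, each in \[0, 1\].
#' @examples
#' spec <- echo_train_spec(6.6, 24, 180)
#' max(abs(epg_cpmg_signal(80, spec) - exp(-spec$te / 80)))
#' @export
epg_cpmg_signal <- function(t2, spec) {
  stopifnot(inherits(spec, "mwi_echo_train"),
            is.numeric(t2), length(t2) == 1, is.finite(t2), t2 > 0)
  etl <- spec$etl
  K <- etl + 1L # configuration orders 0..etl
  e2 <- exp(-spec$echo_spacing / 2 / t2)
  e1 <- exp(-spec$echo_spacing / 2 / spec$t1)

  Fp <- complex(K); Fm <- complex(K); Z <- complex(K)
  Z[1] <- 1 + 0i

  # ideal excitation: 90 deg, phase pi/2 relative to refocusing pulses
  Tx <- epg_rf_matrix(pi / 2, pi / 2)
  s <- c(Fp[1], Fm[1], Z[1])
  s <- Tx %*% s
  Fp[1] <- s[1]; Fm[1] <- s[2]; Z[1] <- s[3]

  Tr <- epg_rf_matrix(spec$alpha_r * pi / 180, 0)
  out <- numeric(etl)
  relax <- function() {
    Fp <<- Fp * e2
    Fm <<- Fm * e2
    Z <<- Z * e1
    Z[1] <<- Z[1] + (1 - e1)
  }
  grad <- function() {
    # shift F+ up one order, F- down one; conjugate symmetry fills F+(0)
    Fp <<- c(0i, Fp[seq_len(K - 1L)])
    Fm <<- c(Fm[-1L], 0i)
    Fp[1] <<- Conj(Fm[1])
  }
  for (k in seq_len(etl)) {
    relax(); grad()
    np <- Tr[1, 1] * Fp + Tr[1, 2] * Fm + Tr[1, 3] * Z
    nm <- Tr[2, 1] * Fp + Tr[2, 2] * Fm + Tr[2, 3] * Z
    nz <- Tr[3, 1] * Fp + Tr[3, 2] * Fm + Tr[3, 3] * Z
    Fp <- np; Fm <- nm; Z <- nz
    relax(); grad()
    out[k] <- Mod(Fp[1])
  }
  out
}

#' Precompute the spin-echo forward operator on a T2 grid
#'
#' Evaluates [epg_cpmg_signal()] for every grid T2 and stores the results
#' as the columns of the discrete SE forward operator `A_SE`
#' (etl x length(grid)). Operators are cached per (spec, grid) pair so that
#' volume fits sharing an acquisition reuse them.
#'
#' @param grid Strictly increasing vector of T2 values in ms (all > 0).
#' @param spec An [echo_train_spec()].
#' @return An object of class `mwi_se_operator`: list with `matrix`
#'   (etl x M, entries in \[0, 1\]), `grid` and `spec`.
#' @export
build_se_operator <- function(grid, spec) {
  stopifnot(inherits(spec, "mwi_echo_train"),
            is.numeric(grid), length(grid) >= 1, all(is.finite(grid)),
            all(grid > 0))
  if (is.unsorted(grid, strictly = TRUE))
    abort("T2 grid must be strictly increasing")
  key <- hash(list("se_op", unclass(spec)[c("echo_spacing", "etl", "alpha_r", "t1")],
                   as.numeric(grid)))
  hit <- get0(key, envir = .op_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  A <- vapply(grid, epg_cpmg_signal, numeric(spec$etl), spec = spec)
  A <- matrix(A, nrow = spec$etl)
  op <- structure(list(matrix = A, grid = as.numeric(grid), spec = spec),
                  class = "mwi_se_operator")
  assign(key, op, envir = .op_cache)
  op
}
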