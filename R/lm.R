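#' One voxel's observed decay data
#'
#' Container pairing the (normalized) ME-SE magnitude decay with its
#' echo-train description and the complex ME-GE decay with its echo times.
#' Either block may be absent when only a single inversion is intended.
#' The effective refocusing angle (nominal times relative B1) lives in
#' `se_spec$alpha_r`.
#'
#' @param se Real ME-SE magnitude signal vector, first-echo magnitude 1.
#' @param se_spec [echo_train_spec()] describing the CPMG train.
#' @param ge Complex ME-GE signal vector, first-echo magnitude 1.
#' @param te_ge ME-GE echo times (ms) or an `mwi_echo_schedule`.
#' @param index Optional voxel index (any scalar or vector label).
#' @return Object of class `mwi_voxel`.
#' @export
voxel_data <- function(se = NULL, se_spec = NULL, ge = NULL, te_ge = NULL,
                       index = NULL) {
  if (!is.null(se)) {
    stopifnot(inherits(se_spec, "mwi_echo_train"), length(se) == se_spec$etl)
    se <- as.numeric(se)
  }
  if (!is.null(ge)) {
    te_ge <- echo_times(te_ge)
    stopifnot(length(ge) == length(te_ge))
    ge <- as.complex(ge)
  }
  structure(list(se = se, se_spec = se_spec, ge = ge, te_ge = te_ge,
                 index = index),
            class = "mwi_voxel")
}

# which unit-signal caches a parameter invalidates
.par_compartment <- c(
  mu1_t2 = "t2_1", sigma1_t2 = "t2_1", mu2_t2 = "t2_2", sigma2_t2 = "t2_2",
  mu1_t2s = "ge_1", sigma1_t2s = "ge_1", mu2_t2s = "ge_2", sigma2_t2s = "ge_2"
)

# assemble the evaluation context: operators, data blocks, weights
build_eval_ctx <- function(voxel, cfg) {
  mode <- cfg$mode
  grid <- relaxation_grid(cfg$n_grid, cfg$grid_range)
  width <- cfg$upper - cfg$lower
  ctx <- list(mode = mode, grid = grid,
              lam_scaled = cfg$lam / ifelse(width > 0, width, 1),
              x_in = cfg$x_in,
              w_se = if (mode == "JOINT") sqrt(cfg$alpha_se) else 1)
  if (mode %in% c("SE", "JOINT")) {
    if (is.null(voxel$se)) abort(paste0("mode ", mode, " requires SE data"))
    ctx$A_se <- build_se_operator(grid$t, voxel$se_spec)$matrix
    ctx$d_se <- voxel$se
  }
  if (mode %in% c("GE_MAG", "GE_CPLX", "JOINT")) {
    if (is.null(voxel$ge)) abort(paste0("mode ", mode, " requires GE data"))
    ctx$A_ge <- build_ge_operator(voxel$te_ge, grid)$matrix
    ctx$tw <- 2e-3 * pi * voxel$te_ge
    ctx$d_ge <- if (mode == "GE_MAG") Mod(voxel$ge) else voxel$ge
  }
  ctx
}

check_normalized <- function(ctx) {
  if (!is.null(ctx$d_se) && abs(ctx$d_se[1] - 1) > 1e-6)
    abort("SE data are not first-echo normalized; call normalize_first_echo()")
  if (!is.null(ctx$d_ge) && abs(Mod(ctx$d_ge[1]) - 1) > 1e-6)
    abort("GE data are not first-echo normalized; call normalize_first_echo()")
  invisible(TRUE)
}

unit_signal <- function(A, mu, sigma, grid) {
  as.vector(A %*% discretize_gaussian(mu, sigma, 1, grid))
}

# evaluate the stacked residual at x, reusing per-compartment unit signals
# from `cache` except those named in `dirty`
eval_residual <- function(x, ctx, cache = NULL, dirty = NULL) {
  mode <- ctx$mode
  u <- if (is.null(cache)) list() else cache
  refresh <- function(slot, A, mu, sigma) {
    if (is.null(u[[slot]]) || slot %in% dirty)
      u[[slot]] <<- unit_signal(A, mu, sigma, ctx$grid)
  }
  parts <- list()
  if (mode %in% c("SE", "JOINT")) {
    refresh("t2_1", ctx$A_se, x[["mu1_t2"]], x[["sigma1_t2"]])
    refresh("t2_2", ctx$A_se, x[["mu2_t2"]], x[["sigma2_t2"]])
    i2 <- x[["i2_t2"]]
    i1 <- i2 * x[["mwf"]] / (1 - x[["mwf"]])
    s_se <- i1 * u$t2_1 + i2 * u$t2_2
    parts$se <- ctx$w_se * (ctx$d_se - s_se)
  }
  if (mode %in% c("GE_MAG", "GE_CPLX", "JOINT")) {
    refresh("ge_1", ctx$A_ge, x[["mu1_t2s"]], x[["sigma1_t2s"]])
    refresh("ge_2", ctx$A_ge, x[["mu2_t2s"]], x[["sigma2_t2s"]])
    i2 <- x[["i2_t2s"]]
    i1 <- i2 * x[["mwf"]] / (1 - x[["mwf"]])
    if (mode == "GE_MAG") {
      s_ge <- i1 * u$ge_1 + i2 * u$ge_2
      parts$ge <- ctx$d_ge - s_ge
    } else {
      s_ge <- (i1 * u$ge_1 * exp(1i * x[["dw1"]] * ctx$tw) +
               i2 * u$ge_2 * exp(1i * x[["dw2"]] * ctx$tw)) * exp(1i * x[["phi0"]])
      r <- ctx$d_ge - s_ge
      parts$ge <- c(Re(r), Im(r))
    }
  }
  parts$lam <- ctx$lam_scaled * (x - ctx$x_in)
  list(r = c(parts$se, parts$ge, parts$lam),
       n_se = length(parts$se), n_ge = length(parts$ge),
       cache = u)
}

#' Stacked residual vector of the regularized inversion
#'
#' Stacks the data-misfit and regularization residuals whose squared norm
#' is the objective of the selected inversion mode:
#' `[sqrt(alpha) * (S_SE - S_SE_hat); Re(S_GE - S_GE_hat);
#'   Im(S_GE - S_GE_hat); lam * (x - x_in) / (upper - lower)]`,
#' with only the blocks active in `cfg$mode` included and the
#' `sqrt(alpha)` SE weight applied in JOINT mode only (the single-SE
#' objective carries no alpha). Complex GE residuals are split into real
#' and imaginary rows, which is also the bookkeeping behind the default
#' `alpha_se = 2`: the complex GE block contributes twice as many rows as
#' the magnitude-only SE block.
#'
#' Signals must be first-echo normalized (magnitude 1 within 1e-6);
#' unnormalized data raise an error.
#'
#' @param x Named parameter vector (or `mwi_model`) matching `cfg$mode`.
#' @param voxel [voxel_data()] carrying the blocks the mode requires.
#' @param cfg [default_config()] object.
#' @return Numeric residual vector.
#' @export
residual_vector <- function(x, voxel, cfg) {
  x <- check_par_vector(x, cfg)
  ctx <- build_eval_ctx(voxel, cfg)
  check_normalized(ctx)
  eval_residual(x, ctx)$r
}

check_par_vector <- function(x, cfg) {
  pars <- model_par_names(cfg$mode)
  x <- unclass(x)
  if (!all(pars %in% names(x)))
    abort(paste0("parameter vector must contain: ", paste(pars, collapse = ", ")))
  x[pars]
}

# finite-difference Jacobian of the stacked residual. Steps are
# fd_rel_step * (upper - lower), reflected to backward differences at the
# upper bound. The regularizer rows are linear, so they are set to
# diag(lam / width) exactly. Only the compartment a parameter touches is
# recomputed per column.
fd_jac <- function(x, ctx, cfg, base) {
  pars <- names(cfg$x_in)
  np <- length(pars)
  nr <- length(base$r)
  nd <- base$n_se + base$n_ge # data rows
  J <- matrix(0, nr, np)
  width <- cfg$upper - cfg$lower
  for (j in seq_len(np)) {
    p <- pars[j]
    if (width[j] == 0) next # frozen parameter: data rows stay zero
    h <- cfg$fd_rel_step * width[j]
    if (x[[p]] + h > cfg$upper[j]) h <- -h
    xj <- x
    xj[[p]] <- xj[[p]] + h
    rj <- eval_residual(xj, ctx, cache = base$cache,
                        dirty = .par_compartment[p])$r
    if (nd > 0) J[seq_len(nd), j] <- (rj[seq_len(nd)] - base$r[seq_len(nd)]) / h
  }
  if (np > 0 && nr > nd)
    J[cbind(nd + seq_len(np), seq_len(np))] <- cfg$lam / ifelse(width > 0, width, 1)
  J
}

#' Finite-difference Jacobian of the residual vector
#'
#' Forward differences with step `fd_rel_step * (upper - lower)` per
#' parameter, reflected to a backward difference where the forward step
#' would leave the feasible box; the (linear) regularizer rows equal
#' `diag(lam / (upper - lower))` exactly. Parameters with a zero-width bound interval are
#' frozen: their data rows are zero.
#'
#' @inheritParams residual_vector
#' @return Matrix of size `n_residuals x n_parameters`.
#' @export
fd_jacobian <- function(x, voxel, cfg) {
  x <- check_par_vector(x, cfg)
  ctx <- build_eval_ctx(voxel, cfg)
  check_normalized(ctx)
  base <- eval_residual(x, ctx)
  fd_jac(x, ctx, cfg, base)
}

#' Regularized bounded Levenberg-Marquardt fit of one voxel
#'
#' Minimizes the stacked residual of [residual_vector()] over the feasible
#' box. Each iteration linearizes the forward model with a
#' finite-difference Jacobian and solves the damped, bound-constrained
#' linear subproblem
#' `min || J d + r ||^2 + damping * || d_scaled ||^2` subject to
#' `lower - x <= d <= upper - x` with an active-set bounded least-squares
#' solver ([bvls()]); the step is scaled by the bound widths for
#' conditioning. Steps that do not decrease the cost trigger a tenfold
#' damping escalation (up to 5 retries per iteration, reusing the
#' Jacobian). Iteration stops on `max_iter`, on a relative cost decrease
#' below `cost_tol`, or on a scaled step norm below `step_tol`; the best
#' visited point is returned, so the result never has higher cost than the
#' initial model.
#'
#' All-zero or non-finite voxel data short-circuit to
#' `status = "degenerate_input"` with `x_hat = x_in`.
#'
#' @param voxel [voxel_data()].
#' @param cfg [default_config()].
#' @return Object of class `mwi_voxel_fit`: list with `x_hat`
#'   (an `mwi_model`), `cost`, `data_residual_se`, `data_residual_ge`,
#'   `n_iter`, `converged`, `status`.
#' @export
lm_fit <- function(voxel, cfg) {
  stopifnot(inherits(voxel, "mwi_voxel"), inherits(cfg, "mwi_config"))
  degenerate <- function() {
    bad <- FALSE
    if (cfg$mode %in% c("SE", "JOINT"))
      bad <- bad || is.null(voxel$se) || !all(is.finite(voxel$se)) || all(voxel$se == 0)
    if (cfg$mode %in% c("GE_MAG", "GE_CPLX", "JOINT"))
      bad <- bad || is.null(voxel$ge) || !all(is.finite(Re(voxel$ge)) & is.finite(Im(voxel$ge))) ||
        all(voxel$ge == 0)
    bad
  }
  mk_result <- function(x, cost, rse, rge, n_iter, converged, status) {
    structure(list(
      x_hat = structure(x, mode = cfg$mode, class = "mwi_model"),
      cost = cost, data_residual_se = rse, data_residual_ge = rge,
      n_iter = n_iter, converged = converged, status = status),
      class = "mwi_voxel_fit")
  }
  if (degenerate())
    return(mk_result(cfg$x_in, NA_real_, NA_real_, NA_real_, 0L, FALSE,
                     "degenerate_input"))
  ctx <- build_eval_ctx(voxel, cfg)
  check_normalized(ctx)
  if (cfg$mode %in% c("GE_CPLX", "JOINT") &&
      identical(cfg$phi0_init, "first_echo_phase")) {
    # the constant phase offset is a nuisance parameter; starting it (and
    # its regularization anchor) at the first-echo phase keeps the fit out
    # of the phase-wrap basin where frequency shifts absorb a large phi0
    p0 <- Arg(voxel$ge[1]) %% (2 * pi)
    p0 <- min(max(p0, cfg$lower[["phi0"]]), cfg$upper[["phi0"]])
    cfg$x_in[["phi0"]] <- p0
    ctx$x_in <- cfg$x_in
  }

  x <- cfg$x_in
  base <- eval_residual(x, ctx)
  cost <- sum(base$r^2)
  if (cost <= .Machine$double.eps^2 * length(base$r)) {
    # the initial model already reproduces the data to machine precision
    return(mk_result(x, cost,
                     if (base$n_se > 0) sqrt(sum((base$r[seq_len(base$n_se)] / ctx$w_se)^2)) else NA_real_,
                     if (base$n_ge > 0) sqrt(sum(base$r[base$n_se + seq_len(base$n_ge)]^2)) else NA_real_,
                     0L, TRUE, "converged_cost"))
  }
  width <- cfg$upper - cfg$lower
  sc <- ifelse(width > 0, width, 1)
  lambda <- cfg$damping
  status <- "max_iter"
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(cfg$max_iter)) {
    n_iter <- it
    J <- fd_jac(x, ctx, cfg, base)
    Js <- J * rep(sc, each = nrow(J))
    accepted <- FALSE
    for (try in 0:5) {
      Ad <- rbind(Js, diag(sqrt(lambda), length(x)))
      bd <- c(-base$r, numeric(length(x)))
      z <- bvls(Ad, bd, (cfg$lower - x) / sc, (cfg$upper - x) / sc)$x
      x_new <- pmin(pmax(x + sc * z, cfg$lower), cfg$upper)
      cand <- eval_residual(x_new, ctx)
      cost_new <- sum(cand$r^2)
      if (is.finite(cost_new) && cost_new < cost) {
        rel <- (cost - cost_new) / max(cost, .Machine$double.xmin)
        step <- sqrt(sum(z^2))
        x <- x_new; base <- cand; cost <- cost_new
        lambda <- max(cfg$damping, lambda / 10)
        accepted <- TRUE
        if (rel <= cfg$cost_tol) { status <- "converged_cost"; converged <- TRUE }
        else if (step <= cfg$step_tol) { status <- "converged_step"; converged <- TRUE }
        break
      }
      lambda <- lambda * 10
    }
    if (!accepted) { status <- "no_decrease"; break }
    if (converged) break
  }
  nd_se <- if (is.null(base$n_se)) 0L else base$n_se
  rse <- if (nd_se > 0) sqrt(sum((base$r[seq_len(nd_se)] / ctx$w_se)^2)) else NA_real_
  rge <- if (base$n_ge > 0)
    sqrt(sum(base$r[nd_se + seq_len(base$n_ge)]^2)) else NA_real_
  mk_result(x, cost, rse, rge, n_iter, converged, status)
}
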