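#' First-echo normalization
#'
#' Divides a decay signal by its first-echo magnitude, so that
#' `|S(TE_min)| = 1` exactly; the complex phase is preserved. This is the
#' normalization contract the inversions require and what makes all fitted
#' parameters invariant under global rescaling of the raw data.
#'
#' @param signal Real or complex signal vector (echoes along the vector).
#' @return Signal of the same type with unit first-echo magnitude.
#' @export
normalize_first_echo <- function(signal) {
  s0 <- Mod(signal[1])
  if (!is.finite(s0) || s0 <= 0)
    abort("first-echo magnitude must be positive; voxel is degenerate")
  signal / s0
}

#' Match the phase of a repeated complex GE scan to the first scan
#'
#' Between repeated ME-GE acquisitions, local frequency and phase drifts
#' (e.g. gradient heating) add an approximately TE-linear phase to the
#' second scan. Per voxel, the TE-dependent phase difference
#' `arg(scan2 * Conj(scan1))` is unwrapped along the echo dimension,
#' fitted with an intercept-plus-slope linear model in TE, and the fitted
#' line is subtracted from scan2's phase, enabling subsequent
#' complex-valued averaging.
#'
#' @param scan1,scan2 Complex arrays of identical shape with echoes along
#'   the last dimension (a plain vector is treated as one voxel).
#' @param te Echo times in ms (length = number of echoes, >= 2).
#' @return `scan2` with the fitted linear phase removed, same shape.
#' @export
phase_match_repeats <- function(scan1, scan2, te) {
  te <- echo_times(te)
  if (length(te) < 2) abort("phase matching needs at least 2 echoes")
  stopifnot(identical(dim(scan1), dim(scan2)),
            length(scan1) == length(scan2))
  d <- dim(scan1)
  vecin <- is.null(d)
  if (vecin) {
    stopifnot(length(scan1) == length(te))
    d <- c(1L, length(te))
    dim(scan1) <- d; dim(scan2) <- d
  }
  ne <- d[length(d)]
  stopifnot(ne == length(te))
  nv <- prod(d[-length(d)])
  m1 <- matrix(scan1, nv, ne)
  m2 <- matrix(scan2, nv, ne)
  dphi <- Arg(m2 * Conj(m1))
  # unwrap along TE: cumulative removal of 2*pi jumps between echoes
  jumps <- dphi[, -1L, drop = FALSE] - dphi[, -ne, drop = FALSE]
  steps <- -2 * pi * round(jumps / (2 * pi))
  un <- dphi
  un[, -1L] <- dphi[, -1L, drop = FALSE] +
    t(apply(steps, 1L, cumsum))
  # per-voxel least-squares line a + b * te (closed form, vectorized)
  X <- cbind(1, te)
  beta <- un %*% X %*% solve(crossprod(X)) # nv x 2: (a, b)
  fitphi <- beta %*% t(X)
  out <- m2 * exp(-1i * fitphi)
  dim(out) <- if (vecin) NULL else dim(scan2)
  out
}

quantize_b1 <- function(b1, step = 0.01) round(b1 / step) * step

#' Voxel-wise inversion of ME-SE / ME-GE volumes
#'
#' Applies [lm_fit()] to every masked voxel of the supplied volumes. Per
#' voxel the effective refocusing angle is the nominal angle scaled by the
#' relative-B1 map (quantized to 0.01 steps so the EPG operator is
#' precomputed once per distinct value); signals are first-echo
#' normalized, then fitted. Masked-out voxels never influence fitted ones,
#' and the result is independent of worker count and iteration order.
#'
#' @param dataset An `mwi_dataset` from [simulate_dataset()], or a list
#'   with any of `se` (array, echoes last), `ge` (complex array), plus
#'   `se_spec` ([echo_train_spec()]) and `ge_te` (echo times) as required
#'   by `cfg$mode`.
#' @param cfg [default_config()]; its `mode` selects which blocks are
#'   fitted.
#' @param mask Logical array over voxels; defaults to the dataset
#'   phantom's mask, else all voxels.
#' @param b1 Relative-B1 array over voxels (1 = nominal); `NULL` assumes
#'   1 everywhere (with a warning when SE data are fitted, since the EPG
#'   model is B1-sensitive).
#' @param workers Number of parallel workers (forked; results identical
#'   for any value).
#' @return Object of class `mwi_fit`: list with `voxels` (a tibble with
#'   one row per fitted voxel: `row`, `col` (and `slice` for 3-D input),
#'   the fitted parameters, `cost`, `data_residual_se`,
#'   `data_residual_ge`, `n_iter`, `converged`, `status`), `cfg`, `dim`,
#'   `mask`, and `truth` (the phantom MWF matrix if available).
#' @export
fit_volume <- function(dataset, cfg, mask = NULL, b1 = NULL, workers = 1L) {
  stopifnot(inherits(cfg, "mwi_config"))
  need_se <- cfg$mode %in% c("SE", "JOINT")
  need_ge <- cfg$mode %in% c("GE_MAG", "GE_CPLX", "JOINT")
  se <- dataset$se; ge <- dataset$ge
  if (need_se && is.null(se)) abort("dataset lacks SE volume required by mode")
  if (need_ge && is.null(ge)) abort("dataset lacks GE volume required by mode")
  ref <- if (!is.null(se)) se else ge
  d <- dim(ref)
  vdim <- d[-length(d)]
  if (is.null(mask)) {
    mask <- if (!is.null(dataset$phantom)) dataset$phantom$mask
            else array(TRUE, vdim)
  }
  stopifnot(identical(as.integer(dim(mask)), as.integer(vdim)))
  if (!any(mask)) abort("mask is empty")
  if (is.null(b1)) {
    if (need_se)
      warn("no relative-B1 map supplied; assuming nominal flip angles (B1 = 1)")
    b1 <- array(1, vdim)
  }
  stopifnot(identical(as.integer(dim(b1)), as.integer(vdim)))

  nv <- prod(vdim)
  se_m <- if (!is.null(se)) matrix(se, nv) else NULL
  ge_m <- if (!is.null(ge)) matrix(ge, nv) else NULL
  te_ge <- if (!is.null(dataset$ge_te)) echo_times(dataset$ge_te) else NULL
  spec0 <- dataset$se_spec
  idx <- which(as.vector(mask))
  b1q <- quantize_b1(as.vector(b1))

  # pre-build one SE operator per distinct quantized B1 value
  if (need_se) {
    grid <- relaxation_grid(cfg$n_grid, cfg$grid_range)
    for (bv in unique(b1q[idx]))
      build_se_operator(grid$t, echo_train_spec(
        spec0$echo_spacing, spec0$etl, spec0$alpha_r * bv, spec0$t1))
  }

  fit_one <- function(v) {
    spec_v <- if (need_se)
      echo_train_spec(spec0$echo_spacing, spec0$etl, spec0$alpha_r * b1q[v],
                      spec0$t1) else spec0
    se_v <- if (need_se) se_m[v, ] else NULL
    ge_v <- if (need_ge) ge_m[v, ] else NULL
    ok <- TRUE
    if (need_se && (!all(is.finite(se_v)) || Mod(se_v[1]) <= 0)) ok <- FALSE
    if (need_ge && (!all(is.finite(Re(ge_v)) & is.finite(Im(ge_v))) ||
                    Mod(ge_v[1]) <= 0)) ok <- FALSE
    if (!ok) {
      return(list(x = cfg$x_in, cost = NA_real_, rse = NA_real_,
                  rge = NA_real_, n_iter = 0L, converged = FALSE,
                  status = "degenerate_input"))
    }
    vox <- voxel_data(
      se = if (need_se) normalize_first_echo(se_v) else NULL,
      se_spec = if (need_se) spec_v else NULL,
      ge = if (need_ge) normalize_first_echo(ge_v) else NULL,
      te_ge = if (need_ge) te_ge else NULL,
      index = v)
    f <- lm_fit(vox, cfg)
    list(x = unclass(f$x_hat), cost = f$cost, rse = f$data_residual_se,
         rge = f$data_residual_ge, n_iter = f$n_iter,
         converged = f$converged, status = f$status)
  }

  res <- if (workers > 1L)
    parallel::mclapply(idx, fit_one, mc.cores = workers)
  else lapply(idx, fit_one)

  coords <- arrayInd(idx, vdim)
  colnames(coords) <- c("row", "col", "slice")[seq_len(ncol(coords))]
  pars <- do.call(rbind, lapply(res, function(z) z$x))
  voxels <- dplyr::bind_cols(
    as_tibble(coords),
    as_tibble(pars),
    tibble(
      cost = vapply(res, function(z) z$cost, numeric(1)),
      data_residual_se = vapply(res, function(z) z$rse, numeric(1)),
      data_residual_ge = vapply(res, function(z) z$rge, numeric(1)),
      n_iter = vapply(res, function(z) z$n_iter, integer(1)),
      converged = vapply(res, function(z) z$converged, logical(1)),
      status = vapply(res, function(z) z$status, character(1))
    )
  )
  structure(list(voxels = voxels, cfg = cfg, dim = vdim, mask = mask,
                 truth = if (!is.null(dataset$phantom)) dataset$phantom$mwf else NULL),
            class = "mwi_fit")
}

#' Extract a fitted parameter as a spatial map
#'
#' @param fit An `mwi_fit` from [fit_volume()].
#' @param parameter Parameter (or diagnostic) column name, e.g. `"mwf"`.
#' @return Numeric array of the fit's spatial dimensions; `NA` outside the
#'   mask.
#' @export
parameter_map <- function(fit, parameter = "mwf") {
  stopifnot(inherits(fit, "mwi_fit"), parameter %in% names(fit$voxels))
  out <- array(NA_real_, fit$dim)
  out[as.matrix(fit$voxels[, seq_along(fit$dim)])] <-
    as.numeric(fit$voxels[[parameter]])
  out
}

#' Difference map and summary error metrics of an MWF estimate
#'
#' @param est Estimated MWF array (e.g. [parameter_map()] output).
#' @param truth Ground-truth MWF array of the same shape.
#' @param mask Logical array selecting the evaluated voxels.
#' @return List with `difference` (est - truth, `NA` outside mask) and
#'   `metrics`, a one-row tibble with `bias`, `mae`, `rmse`, `n_voxels`.
#' @export
error_maps <- function(est, truth, mask = NULL) {
  stopifnot(identical(dim(est), dim(truth)))
  if (is.null(mask)) mask <- !is.na(est)
  stopifnot(identical(dim(mask), dim(est)))
  if (!any(mask)) abort("mask is empty")
  diffm <- est - truth
  diffm[!mask] <- NA_real_
  dv <- diffm[mask]
  list(
    difference = diffm,
    metrics = tibble(
      bias = mean(dv), mae = mean(abs(dv)), rmse = sqrt(mean(dv^2)),
      n_voxels = sum(mask))
  )
}

#' Per-ROI statistics of fitted parameter maps
#'
#' Computes mean and sample standard deviation (n - 1 convention) of each
#' fitted parameter over each labelled region of interest, in the native
#' voxel space (no resampling).
#'
#' @param fit An `mwi_fit` from [fit_volume()].
#' @param roi_labels Integer array over voxels; 0 = unlabeled.
#' @param names Optional named character vector or data frame
#'   (`label`, `name`) naming the labels; unknown labels in `names` are
#'   skipped with a warning.
#' @param parameters Character vector of parameter columns to summarize;
#'   defaults to all model parameters of the fit's mode.
#' @return Tibble with columns `roi`, `label`, `parameter`, `n_voxels`,
#'   `mean`, `sd`.
#' @export
roi_stats <- function(fit, roi_labels, names = NULL, parameters = NULL) {
  stopifnot(inherits(fit, "mwi_fit"))
  stopifnot(identical(as.integer(dim(roi_labels)), as.integer(fit$dim)))
  if (is.null(parameters)) parameters <- model_par_names(fit$cfg$mode)
  lab_at <- roi_labels[as.matrix(fit$voxels[, seq_along(fit$dim)])]
  present <- sort(unique(lab_at[lab_at != 0]))
  if (is.data.frame(names)) names <- setNames(names$name, names$label)
  if (!is.null(names)) {
    unknown <- setdiff(as.integer(base::names(names)), present)
    if (length(unknown))
      warn(paste0("ROI labels absent from the volume skipped: ",
                  paste(unknown, collapse = ", ")))
  }
  vox <- fit$voxels
  vox$..label <- lab_at
  out <- vox |>
    dplyr::filter(.data$..label != 0) |>
    tidyr::pivot_longer(dplyr::all_of(parameters),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(label = .data$..label, .data$parameter) |>
    dplyr::summarise(n_voxels = dplyr::n(),
                     mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop")
  out$roi <- if (!is.null(names)) {
    nm <- names[as.character(out$label)]
    ifelse(is.na(nm), paste0("roi_", out$label), nm)
  } else paste0("roi_", out$label)
  dplyr::select(out, "roi", "label", "parameter", "n_voxels", "mean", "sd")
}
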