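#' Tidy a volume fit into a long tibble
#'
#' @param x An `mwi_fit` from [fit_volume()].
#' @param ... Unused.
#' @return Tibble with one row per voxel and parameter: voxel coordinates,
#'   `parameter`, `estimate`, plus `truth_mwf` for the `mwf` rows when the
#'   dataset carried ground truth.
#' @export
tidy.mwi_fit <- function(x, ...) {
  pars <- model_par_names(x$cfg$mode)
  coords <- names(x$voxels)[seq_along(x$dim)]
  out <- x$voxels |>
    dplyr::select(dplyr::all_of(c(coords, pars))) |>
    tidyr::pivot_longer(dplyr::all_of(pars),
                        names_to = "parameter", values_to = "estimate")
  if (!is.null(x$truth)) {
    tr <- x$truth[as.matrix(x$voxels[, seq_along(x$dim)])]
    key <- dplyr::bind_cols(x$voxels[, seq_along(x$dim)], truth_mwf = tr)
    out <- dplyr::left_join(out, key, by = coords)
    out$truth_mwf[out$parameter != "mwf"] <- NA_real_
  }
  out
}

#' One-row summary of a volume fit
#'
#' @param x An `mwi_fit`.
#' @param ... Unused.
#' @return Tibble with `mode`, `n_voxels`, `prop_converged`,
#'   `median_iter`, `mean_cost`, and, when ground truth is available,
#'   `mwf_bias`, `mwf_mae`, `mwf_rmse`.
#' @export
glance.mwi_fit <- function(x, ...) {
  v <- x$voxels
  out <- tibble(
    mode = x$cfg$mode,
    n_voxels = nrow(v),
    prop_converged = mean(v$converged),
    median_iter = stats::median(v$n_iter),
    mean_cost = mean(v$cost, na.rm = TRUE)
  )
  if (!is.null(x$truth)) {
    ev <- error_maps(parameter_map(x, "mwf"), x$truth, x$mask)
    out$mwf_bias <- ev$metrics$bias
    out$mwf_mae <- ev$metrics$mae
    out$mwf_rmse <- ev$metrics$rmse
  }
  out
}

#' Plot a fitted parameter map
#'
#' @param object An `mwi_fit`.
#' @param parameter Parameter to display (default `"mwf"`).
#' @param ... Unused.
#' @return A ggplot raster of the parameter map.
#' @export
autoplot.mwi_fit <- function(object, parameter = "mwf", ...) {
  coords <- names(object$voxels)[seq_along(object$dim)]
  df <- object$voxels[, c(coords, parameter)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data[[parameter]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = parameter) +
    ggplot2::theme_minimal()
}

#' Estimated-versus-true MWF scatter plot
#'
#' Mirrors the standard accuracy display for phantom simulations: voxel
#' MWF estimates against the ground truth with the identity line; points
#' close to the identity indicate an accurate inversion.
#'
#' @param fits A named list of `mwi_fit` objects (names label methods).
#' @return A ggplot object.
#' @export
plot_mwf_scatter <- function(fits) {
  if (inherits(fits, "mwi_fit")) fits <- list(fit = fits)
  df <- purrr::imap_dfr(fits, function(f, nm) {
    stopifnot(!is.null(f$truth))
    tibble(method = nm,
           true_mwf = f$truth[as.matrix(f$voxels[, seq_along(f$dim)])],
           est_mwf = f$voxels$mwf)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$true_mwf, .data$est_mwf,
                                   colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "true MWF", y = "estimated MWF") +
    ggplot2::theme_minimal()
}

#' @export
print.mwi_fit <- function(x, ...) {
  cat(sprintf("<mwi_fit> mode %s, %d voxels over %s grid, %.1f%% converged\n",
              x$cfg$mode, nrow(x$voxels), paste(x$dim, collapse = "x"),
              100 * mean(x$voxels$converged)))
  print(utils::head(x$voxels))
  invisible(x)
}

#' @export
print.mwi_voxel_fit <- function(x, ...) {
  cat(sprintf("<mwi_voxel_fit> %s: cost %.4g after %d iterations (%s)\n",
              attr(x$x_hat, "mode"), x$cost, x$n_iter, x$status))
  print(round(unclass(x$x_hat), 4))
  invisible(x)
}
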