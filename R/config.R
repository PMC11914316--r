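.table1 <- local({
  # parameter, initial value, lower, upper, in-vivo regularization
  p <- list(
    mu1_t2     = c(18,   5,   35,  0.02),
    sigma1_t2  = c(0.1,  0.1, 5,   0.01),
    mu2_t2     = c(80,   45,  180, 0.02),
    sigma2_t2  = c(0.1,  0.1, 5,   0.01),
    i2_t2      = c(2,    0.1, 5,   0.01),
    mwf        = c(0.1,  0,   0.85, 0.01),
    mu1_t2s    = c(10,   5,   25,  0.02),
    sigma1_t2s = c(0.1,  0.1, 5,   0.01),
    dw1        = c(-5,  -75,  75,  0.02),
    mu2_t2s    = c(60,   45,  180, 0.02),
    sigma2_t2s = c(0.1,  0.1, 5,   0.01),
    i2_t2s     = c(1,    0.1, 5,   0.01),
    dw2        = c(0,   -75,  75,  0.01),
    phi0       = c(0,    0,   2 * pi, 0.01)
  )
  m <- do.call(rbind, p)
  colnames(m) <- c("init", "lower", "upper", "lam_invivo")
  m
})

#' Reference model parameter table
#'
#' Initial values, box bounds and the in-vivo regularization weights of the
#' 14-parameter two-pool model (T2 units in ms, frequency shifts in Hz,
#' phase in rad, integrals and MWF dimensionless).
#'
#' @return A tibble with columns `parameter`, `init`, `lower`, `upper`,
#'   `lam_invivo`.
#' @export
model_parameter_table <- function() {
  as_tibble(.table1, rownames = NA) |>
    tibble::rownames_to_column("parameter") |>
    as_tibble()
}

#' Build an inversion configuration
#'
#' Assembles initial model, bounds, regularization and optimizer controls
#' for one of the four inversion modes. `setting = "simulation"` uses a
#' flat regularization of 0.01 on all parameters; `setting = "invivo"` uses
#' the slightly stronger weights on the compartment means and the myelin
#' frequency shift (0.02; all others 0.01).
#'
#' The regularizer penalizes `lam * (x - x_in) / (upper - lower)`, i.e.
#' dimensionless bound-width-scaled deviations from the initial model, so
#' that a given lambda weights all parameters comparably regardless of
#' their native units, and pulls the solution towards the initial model
#' rather than towards zero.
#'
#' @param mode One of `"SE"`, `"GE_MAG"`, `"GE_CPLX"`, `"JOINT"`.
#' @param setting `"simulation"` or `"invivo"` (selects the lambda regime).
#' @param ... Overrides for any configuration field: `x_in`, `lower`,
#'   `upper`, `lam` (full vectors or named partial vectors), `alpha_se`,
#'   `damping`, `fd_rel_step`, `max_iter`, `cost_tol`, `step_tol`,
#'   `phi0_init` (`"first_echo_phase"` starts the constant phase offset --
#'   and its regularization anchor -- at the phase of the voxel's first GE
#'   echo, avoiding a phase-wrap local minimum; `"fixed"` keeps the `x_in`
#'   value), `n_grid`, `grid_range`.
#' @return Object of class `mwi_config`.
#' @examples
#' cfg <- default_config("JOINT", "simulation")
#' cfg$x_in
#' @export
default_config <- function(mode = c("JOINT", "SE", "GE_MAG", "GE_CPLX"),
                           setting = c("simulation", "invivo"), ...) {
  mode <- match.arg(mode)
  setting <- match.arg(setting)
  pars <- model_par_names(mode)
  tab <- .table1[pars, , drop = FALSE]
  lam <- if (setting == "simulation") setNames(rep(0.01, length(pars)), pars)
         else setNames(tab[, "lam_invivo"], pars)
  cfg <- list(
    mode = mode,
    setting = setting,
    x_in = setNames(tab[, "init"], pars),
    lower = setNames(tab[, "lower"], pars),
    upper = setNames(tab[, "upper"], pars),
    lam = lam,
    alpha_se = 2,
    damping = 0.01,
    fd_rel_step = 1e-4,
    max_iter = 50L,
    cost_tol = 1e-10,
    step_tol = 1e-8,
    phi0_init = "first_echo_phase",
    n_grid = 360L,
    grid_range = c(0.2, 400)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) abort(paste0("unknown config field: ", nm))
    if (nm %in% c("x_in", "lower", "upper", "lam") && !is.null(names(over[[nm]]))) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  validate_config(cfg)
}

#' @rdname default_config
#' @param x An object to validate.
#' @export
validate_config <- function(x) {
  pars <- model_par_names(x$mode)
  for (f in c("x_in", "lower", "upper", "lam"))
    if (!identical(names(x[[f]]), pars))
      abort(paste0("config field ", f, " must be named with: ",
                   paste(pars, collapse = ", ")))
  if (any(x$lower > x$upper)) abort("lower bounds exceed upper bounds")
  if (any(x$x_in < x$lower | x$x_in > x$upper))
    abort("initial model x_in must satisfy lower <= x_in <= upper")
  if (any(x$lam < 0)) abort("lam must be nonnegative")
  if (!x$phi0_init %in% c("first_echo_phase", "fixed"))
    abort("phi0_init must be 'first_echo_phase' or 'fixed'")
  stopifnot(x$alpha_se > 0, x$damping >= 0, x$fd_rel_step > 0,
            x$max_iter >= 1, x$cost_tol >= 0, x$step_tol >= 0)
  class(x) <- "mwi_config"
  x
}

#' Read / write an inversion configuration as YAML or JSON
#'
#' Configurations round-trip through a flat-keyed file; vector fields are
#' stored as named maps. The format is inferred from the file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param cfg An `mwi_config`.
#' @param path File path.
#' @return `write_config()` the path, invisibly; `read_config()` an
#'   `mwi_config`.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$max_iter <- as.integer(x$max_iter)
  x <- lapply(x, function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("x_in", "lower", "upper", "lam"))
    x[[f]] <- unlist(x[[f]])
  x$grid_range <- as.numeric(unlist(x$grid_range))
  x$max_iter <- as.integer(x$max_iter)
  cfg <- default_config(x$mode, x$setting)
  for (nm in setdiff(names(x), c("mode", "setting")))
    cfg[[nm]] <- x[[nm]]
  validate_config(cfg)
}
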