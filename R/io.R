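write_nii <- function(x, path) {
  RNifti::writeNifti(RNifti::asNifti(x), path)
  invisible(path)
}

read_nii <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  # drop the NIfTI header attributes and any trailing singleton dims so the
  # result is a plain numeric array
  d <- dim(arr)
  while (length(d) > 2 && d[length(d)] == 1) d <- d[-length(d)]
  out <- as.vector(arr)
  dim(out) <- d
  out
}

manifest_entry <- function(dir, files) {
  lapply(setNames(files, files), function(f) {
    p <- file.path(dir, f)
    list(md5 = unname(tools::md5sum(p)), bytes = file.size(p))
  })
}

#' Write / read a simulated dataset directory
#'
#' Serializes an `mwi_dataset` as NIfTI volumes (SE magnitude; GE real and
#' imaginary parts as paired volumes; ground-truth MWF map and mask), JSON
#' sidecars for the acquisition specs, run parameters and seeds, and a
#' manifest tying everything together (file hashes, package version).
#'
#' @param dataset An `mwi_dataset` from [simulate_dataset()].
#' @param dir Output directory.
#' @param overwrite Overwrite an existing dataset directory?
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns an `mwi_dataset`.
#' @export
write_dataset <- function(dataset, dir, overwrite = FALSE) {
  stopifnot(inherits(dataset, "mwi_dataset"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    abort(paste0("output directory ", dir, " is not empty; use overwrite = TRUE"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nii(dataset$se, file.path(dir, "se.nii.gz"))
  write_nii(Re(dataset$ge), file.path(dir, "ge_real.nii.gz"))
  write_nii(Im(dataset$ge), file.path(dir, "ge_imag.nii.gz"))
  write_nii(dataset$phantom$mwf, file.path(dir, "truth_mwf.nii.gz"))
  write_nii(dataset$phantom$mask * 1, file.path(dir, "mask.nii.gz"))
  sp <- dataset$se_spec
  jsonlite::write_json(list(
    se_spec = sp[c("echo_spacing", "etl", "alpha_r", "t1")],
    ge_te = echo_times(dataset$ge_te),
    snr = dataset$snr, seed_noise = dataset$seed_noise,
    phantom = dataset$phantom[c("style", "seed")],
    run = as.list(dataset$run[1, ])
  ), file.path(dir, "sidecar.json"), auto_unbox = TRUE, digits = NA)
  files <- c("se.nii.gz", "ge_real.nii.gz", "ge_imag.nii.gz",
             "truth_mwf.nii.gz", "mask.nii.gz", "sidecar.json")
  jsonlite::write_json(list(
    kind = "mwi_dataset",
    package_version = as.character(utils::packageVersion("mwijoint")),
    files = manifest_entry(dir, files)
  ), file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "sidecar.json"), simplifyVector = TRUE)
  se <- read_nii(file.path(dir, "se.nii.gz"))
  gr <- read_nii(file.path(dir, "ge_real.nii.gz"))
  gi <- read_nii(file.path(dir, "ge_imag.nii.gz"))
  mwf <- read_nii(file.path(dir, "truth_mwf.nii.gz"))
  run <- as_tibble(as.list(sc$run))
  class(run) <- c("mwi_run_params", class(run))
  phantom <- structure(list(mwf = mwf, mask = mwf > 0,
                            style = sc$phantom$style,
                            seed = sc$phantom$seed),
                       class = "mwi_phantom")
  structure(list(
    se = se,
    ge = array(complex(real = gr, imaginary = gi), dim(gr)),
    phantom = phantom,
    run = run,
    se_spec = echo_train_spec(sc$se_spec$echo_spacing, sc$se_spec$etl,
                              sc$se_spec$alpha_r, sc$se_spec$t1),
    ge_te = as.numeric(sc$ge_te),
    snr = sc$snr, seed_noise = sc$seed_noise
  ), class = "mwi_dataset")
}

#' Write fitted parameter maps to a directory
#'
#' One NIfTI volume per fitted parameter plus cost / iteration / status
#' volumes, the per-voxel table as CSV, the configuration, and a manifest.
#'
#' @param fit An `mwi_fit` from [fit_volume()].
#' @param dir Output directory.
#' @param overwrite Overwrite existing outputs?
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir, overwrite = FALSE) {
  stopifnot(inherits(fit, "mwi_fit"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    abort(paste0("output directory ", dir, " is not empty; use overwrite = TRUE"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pars <- model_par_names(fit$cfg$mode)
  files <- character(0)
  for (p in c(pars, "cost", "n_iter")) {
    f <- paste0(p, ".nii.gz")
    write_nii(parameter_map(fit, p), file.path(dir, f))
    files <- c(files, f)
  }
  utils::write.csv(fit$voxels, file.path(dir, "voxels.csv"), row.names = FALSE)
  write_config(fit$cfg, file.path(dir, "config.json"))
  files <- c(files, "voxels.csv", "config.json")
  jsonlite::write_json(list(
    kind = "mwi_fit", mode = fit$cfg$mode,
    package_version = as.character(utils::packageVersion("mwijoint")),
    dim = fit$dim,
    files = manifest_entry(dir, files)
  ), file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
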