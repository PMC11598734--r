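# Spectrum comparison metrics, the grid-scan parameterization workflow,
# pseudo-experimental spectrum generation, and file interfaces (spectrum
# CSV, YAML configuration).

#' Compare a model spectrum with a reference spectrum
#'
#' The reference reflectance is linearly interpolated onto the model grid
#' over the overlapping wavelength range. `R2` is the coefficient of
#' determination `1 - SS_res / SS_tot` (with `SS_tot` about the reference
#' mean), which penalizes systematic bias and not only shape mismatch -
#' unlike squared Pearson correlation, which is invariant to offset and
#' scale. `RMSE` is the root mean square residual in reflectance-fraction
#' units.
#'
#' @param model A [leaf_spectrum()] (or data frame with `wavelength` and
#'   `reflectance`).
#' @param reference Reference spectrum, same layout.
#' @return List with `R2` and `RMSE`.
#' @export
compare_spectra <- function(model, reference) {
  lo <- max(min(model$wavelength), min(reference$wavelength))
  hi <- min(max(model$wavelength), max(reference$wavelength))
  keep <- model$wavelength >= lo & model$wavelength <= hi
  if (sum(keep) < 3) stop("fewer than 3 overlapping wavelengths")
  wl <- model$wavelength[keep]
  mod <- model$reflectance[keep]
  ref <- stats::approx(reference$wavelength, reference$reflectance,
                       xout = wl)$y
  res <- ref - mod
  ss_res <- sum(res^2)
  ss_tot <- sum((ref - mean(ref))^2)
  list(R2 = 1 - ss_res / ss_tot, RMSE = sqrt(mean(res^2)))
}

#' Grid scan of model parameters against a reference spectrum
#'
#' Runs one forward simulation per point of a parameter grid and ranks the
#' points by agreement with the reference spectrum. This mirrors the manual
#' parameterization workflow: scan the spongy scattering coefficient, then
#' pigment corrections, then the rough-surface fraction, keeping the best
#' value at each stage.
#'
#' @param grid Named list of value vectors, e.g.
#'   `list(s_Sp = c(400, 600, 800, 1000))`. Multiple names yield the full
#'   factorial grid. Units follow [update_leaf_params()] (degrees, um).
#' @param params Base [leaf_params()]; each grid point overrides its named
#'   fields.
#' @param reference Reference spectrum (data frame with `wavelength`,
#'   `reflectance`).
#' @param spectra Specific absorption spectra for the forward runs.
#' @param N Iteration count; defaults to `params$N`.
#' @return Data frame with one row per grid point: the parameter values,
#'   `R2` and `RMSE`, sorted by `R2` descending.
#' @export
scan_parameters <- function(grid, params, reference,
                            spectra = fixture_spectra(), N = params$N) {
  stopifnot(is.list(grid), length(grid) > 0, !is.null(names(grid)),
            all(nzchar(names(grid))), all(lengths(grid) > 0))
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  metrics <- lapply(seq_len(nrow(pts)), function(i) {
    p <- do.call(update_leaf_params,
                 c(list(params), as.list(pts[i, , drop = FALSE])))
    compare_spectra(simulate_spectrum(p, spectra, N = N), reference)
  })
  out <- cbind(pts,
               R2 = vapply(metrics, `[[`, numeric(1), "R2"),
               RMSE = vapply(metrics, `[[`, numeric(1), "RMSE"))
  out[order(-out$R2), , drop = FALSE]
}

#' Generate a pseudo-experimental reflectance spectrum
#'
#' Forward-simulates a spectrum and adds i.i.d. Gaussian noise to the
#' reflectance (clipped at zero), emulating a measured spectrum with known
#' generating parameters - the fixture used for parameter-recovery tests in
#' place of instrument data.
#'
#' @param params Generating [leaf_params()].
#' @param noise_sd Noise standard deviation in reflectance-fraction units.
#' @param seed Integer seed; the output is reproducible per seed.
#' @param spectra Specific absorption spectra for the forward run.
#' @return A `leaf_spectrum` data frame (the `transmittance` column is the
#'   noise-free model transmittance).
#' @export
make_pseudo_experimental <- function(params, noise_sd = 0.005, seed = 1,
                                     spectra = fixture_spectra()) {
  stopifnot(noise_sd >= 0)
  s <- simulate_spectrum(params, spectra)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    s$reflectance <- pmax(0, s$reflectance +
                            stats::rnorm(nrow(s), 0, noise_sd))
    s$absorptance <- 1 - s$reflectance - s$transmittance
  }
  s
}

#' Read a reflectance spectrum from CSV
#'
#' Expected columns: `wavelength_nm` and `reflectance` (fraction), with an
#' optional `transmittance`. A column named `reflectance_percent` (or
#' values evidently on a 0-100 scale) is converted to fractions with a
#' message.
#'
#' @param file Path to the CSV file.
#' @return A `leaf_spectrum` data frame.
#' @export
read_spectrum_csv <- function(file) {
  d <- utils::read.csv(file)
  if (!"wavelength_nm" %in% names(d))
    stop("spectrum CSV must have a wavelength_nm column")
  refl <- NULL
  if ("reflectance" %in% names(d)) {
    refl <- d$reflectance
    if (max(refl, na.rm = TRUE) > 1.5) {
      message("reflectance values exceed 1; interpreting as percent")
      refl <- refl / 100
    }
  } else if ("reflectance_percent" %in% names(d)) {
    message("reading reflectance_percent column as percent")
    refl <- d$reflectance_percent / 100
  } else {
    stop("spectrum CSV must have a reflectance or reflectance_percent column")
  }
  tr <- if ("transmittance" %in% names(d)) d$transmittance else NA_real_
  leaf_spectrum(d$wavelength_nm, refl, tr)
}

#' Write a reflectance spectrum to CSV
#'
#' @param spectrum A `leaf_spectrum` data frame.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, file) {
  d <- data.frame(wavelength_nm = spectrum$wavelength,
                  reflectance = spectrum$reflectance)
  if (!all(is.na(spectrum$transmittance)))
    d$transmittance <- spectrum$transmittance
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' Read model parameters from a YAML configuration file
#'
#' Accepts any subset of the [leaf_params()] arguments (same names and
#' units); unspecified parameters keep their defaults.
#'
#' @param file Path to a YAML file.
#' @return A [leaf_params()] object.
#' @export
read_leaf_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg)) cfg <- list()
  known <- names(formals(leaf_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(leaf_params, cfg)
}
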