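# Wavelength-dependent absorption coefficients of the two mesophyll layers,
# built from pigment concentrations and specific absorption spectra of
# chlorophyll a, chlorophyll b and carotenoids, plus the conversion between
# palisade-layer and whole-leaf average concentrations.

#' Synthetic or user-supplied specific absorption spectra
#'
#' Published in-vivo specific absorption curves of the three pigment pools
#' are available as figures rather than tables, so the package ships a
#' documented synthetic stand-in: each pigment is a sum of Gaussian bands
#' at its canonical absorption maxima (chlorophyll a near 430 and 662 nm,
#' chlorophyll b near 460 and 644 nm, carotenoids near 450 and 480 nm) plus
#' a broad low-amplitude green-region tail for the chlorophylls, truncated
#' to zero above 720 nm. Amplitudes (cm^2 mg^-1) are chosen so that the
#' forward model with the default pea-leaf parameter set produces the
#' canonical leaf reflectance shape: local green maximum, deep red trough
#' near 680 nm and a near-infrared plateau. For quantitative work supply
#' measured spectra via `file`.
#'
#' @param kind `"gaussian_default"` for the synthetic fixture or `"file"`
#'   to load a CSV (see [read_pigment_csv()] for the format).
#' @param file Path to a pigment CSV when `kind = "file"`.
#' @param wavelengths Wavelength grid in nm for the synthetic fixture.
#' @return Object of class `pigment_spectra`: data frame with columns
#'   `wavelength`, `a_ChA`, `a_ChB`, `a_Car` and a `provenance` attribute.
#' @export
fixture_spectra <- function(kind = c("gaussian_default", "file"),
                            file = NULL, wavelengths = 400:800) {
  kind <- match.arg(kind)
  if (kind == "file") {
    if (is.null(file)) stop("kind = 'file' requires a file path")
    return(read_pigment_csv(file))
  }
  gauss <- function(wl, peaks) {
    v <- numeric(length(wl))
    for (p in peaks) v <- v + p[3] * exp(-((wl - p[1]) / p[2])^2 / 2)
    v[wl > 720] <- 0
    v
  }
  wl <- wavelengths
  s <- data.frame(
    wavelength = wl,
    # peaks: centre nm, sigma nm, amplitude cm^2 mg^-1; the Soret and red
    # maxima sit at their in-vivo positions, and a broad low shoulder keeps
    # the green window partially absorbing as measured leaf spectra are
    a_ChA = gauss(wl, list(c(430, 22, 68), c(668, 14, 60), c(590, 65, 10))),
    a_ChB = gauss(wl, list(c(460, 18, 52), c(650, 13, 28), c(590, 55, 8))),
    a_Car = gauss(wl, list(c(450, 17, 60), c(480, 15, 55))))
  attr(s, "provenance") <- "synthetic Gaussian-band fixture"
  class(s) <- c("pigment_spectra", "data.frame")
  s
}

#' Read specific absorption spectra from CSV
#'
#' Expected columns: `wavelength_nm`, `a_chla_cm2_per_mg`,
#' `a_chlb_cm2_per_mg`, `a_car_cm2_per_mg`, with a header row.
#'
#' @param file Path to the CSV file.
#' @return A `pigment_spectra` data frame (see [fixture_spectra()]).
#' @export
read_pigment_csv <- function(file) {
  d <- utils::read.csv(file)
  need <- c("wavelength_nm", "a_chla_cm2_per_mg", "a_chlb_cm2_per_mg",
            "a_car_cm2_per_mg")
  if (!all(need %in% names(d)))
    stop("pigment CSV must have columns: ", paste(need, collapse = ", "))
  if (any(diff(d$wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(d[need[-1]] < 0)) stop("specific absorption must be >= 0")
  s <- data.frame(wavelength = d$wavelength_nm, a_ChA = d$a_chla_cm2_per_mg,
                  a_ChB = d$a_chlb_cm2_per_mg, a_Car = d$a_car_cm2_per_mg)
  attr(s, "provenance") <- paste0("user file: ", file)
  class(s) <- c("pigment_spectra", "data.frame")
  s
}

#' Write specific absorption spectra to CSV
#'
#' @param spectra A `pigment_spectra` data frame.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_pigment_csv <- function(spectra, file) {
  d <- data.frame(wavelength_nm = spectra$wavelength,
                  a_chla_cm2_per_mg = spectra$a_ChA,
                  a_chlb_cm2_per_mg = spectra$a_ChB,
                  a_car_cm2_per_mg = spectra$a_Car)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

# linear interpolation onto a target grid; wavelengths outside the source
# range absorb nothing
.interp_pigment <- function(wl_src, val, wl_out) {
  v <- stats::approx(wl_src, val, xout = wl_out, rule = 1)$y
  v[is.na(v)] <- 0
  v
}

#' Palisade absorption coefficient spectrum
#'
#' Pointwise linear combination of the specific absorption spectra weighted
#' by the palisade pigment concentrations:
#' `a_P(lambda) = C_ChA a_ChA + C_ChB a_ChB + C_Car a_Car`, in cm^-1.
#'
#' @param pigments A [leaf_params()] object or any list with fields
#'   `C_ChA`, `C_ChB`, `C_Car` (mg cm^-3).
#' @param spectra Specific absorption spectra ([fixture_spectra()]).
#' @param wavelengths Output grid in nm; spectra are linearly interpolated.
#' @return Vector of absorption coefficients, cm^-1.
#' @export
palisade_absorption <- function(pigments, spectra = fixture_spectra(),
                                wavelengths = 400:800) {
  wl <- spectra$wavelength
  outside <- wavelengths < min(wl) | wavelengths > max(wl)
  if (any(outside))
    warning(sprintf("%d wavelength(s) outside the supplied pigment spectra; using zero absorption there",
                    sum(outside)))
  pigments$C_ChA * .interp_pigment(wl, spectra$a_ChA, wavelengths) +
    pigments$C_ChB * .interp_pigment(wl, spectra$a_ChB, wavelengths) +
    pigments$C_Car * .interp_pigment(wl, spectra$a_Car, wavelengths)
}

#' Spongy absorption coefficient spectrum
#'
#' The spongy layer carries a fixed fraction `N_SpP` of the palisade
#' pigment concentration, so its absorption spectrum is the palisade one
#' scaled pointwise.
#'
#' @param a_P Palisade absorption coefficient(s), cm^-1.
#' @param N_SpP Spongy/palisade pigment-concentration ratio.
#' @return Vector of absorption coefficients, cm^-1.
#' @export
spongy_absorption <- function(a_P, N_SpP = 0.2) {
  stopifnot(N_SpP >= 0)
  N_SpP * a_P
}

#' Leaf-average pigment concentration from the palisade concentration
#'
#' Thickness-weighted average over the two layers, with the spongy layer at
#' a fraction `N_SpP` of the palisade concentration:
#' `C_av = C * (h/(h+l) + N_SpP * l/(h+l))`.
#'
#' @param C Palisade-layer concentration, mg cm^-3.
#' @param h,l Palisade and spongy thicknesses (any common unit).
#' @param N_SpP Spongy/palisade pigment-concentration ratio.
#' @return Whole-leaf average concentration, mg cm^-3.
#' @export
average_concentration <- function(C, h, l, N_SpP = 0.2) {
  if (h + l <= 0) stop("h + l must be positive")
  C * (h / (h + l) + N_SpP * l / (h + l))
}

#' Palisade concentration from the leaf-average concentration
#'
#' Inverse of [average_concentration()].
#'
#' @param C_av Whole-leaf average concentration, mg cm^-3.
#' @inheritParams average_concentration
#' @return Palisade-layer concentration, mg cm^-3.
#' @export
layer_concentration <- function(C_av, h, l, N_SpP = 0.2) {
  if (h + l <= 0) stop("h + l must be positive")
  C_av / (h / (h + l) + N_SpP * l / (h + l))
}
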