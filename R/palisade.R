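# Beer-Bouguer-Lambert propagation through the palisade mesophyll. The
# palisade scatters weakly (s_P ~ 5 cm^-1 against ~600-1000 cm^-1 in the
# spongy layer), so collimated and scattered flows are attenuated by
# absorption only, and single scattering of the two downward flows feeds a
# closed-form backscatter source into the upward scattered flow.

#' Palisade layer parameters
#'
#' @param h Layer thickness in cm (use [um_to_cm()] for micrometres).
#' @param s_P Scattering coefficient, cm^-1. Default 5.
#' @param f Asymmetry factor in `[0, 1]`: fraction of scattered light that
#'   continues into the forward hemisphere. 0.5 means isotropic
#'   redistribution.
#' @return Object of class `palisade_params`.
#' @export
palisade_params <- function(h, s_P = 5, f = 0.5) {
  stopifnot(h >= 0, s_P >= 0, f >= 0, f <= 1)
  structure(list(h = h, s_P = s_P, f = f), class = "palisade_params")
}

#' Convert micrometres to centimetres
#'
#' Thicknesses are configured in micrometres but all attenuation
#' coefficients are per centimetre; internal lengths are kept in cm.
#' @param x Length in micrometres.
#' @return Length in centimetres.
#' @export
um_to_cm <- function(x) x * 1e-4

#' Downward attenuation through the palisade layer
#'
#' The forward collimated flow travels at the internal refraction angle and
#' is attenuated over the slant path `h / cos(beta_I1)`; the forward
#' scattered flow uses a mean path-length factor of 2 (hemispherical
#' averaging of diffuse propagation directions).
#'
#' @param I_C0,I_S0 Collimated and scattered flux at the top of the layer.
#'   May be vectors (e.g. one value per wavelength).
#' @param p [palisade_params()].
#' @param a_P Absorption coefficient, cm^-1; scalar or vector matching the
#'   fluxes.
#' @param beta_I1 Internal propagation angle of the collimated flow, rad.
#' @return List with `I_C_h` and `I_S_h`, fluxes at the bottom of the layer.
#' @export
palisade_forward <- function(I_C0, I_S0, p, a_P, beta_I1) {
  if (cos(beta_I1) <= 1e-9) stop("grazing internal angle: degenerate path")
  if (any(I_C0 < 0) || any(I_S0 < 0)) stop("fluxes must be >= 0")
  list(I_C_h = I_C0 * exp(-a_P * p$h / cos(beta_I1)),
       I_S_h = I_S0 * exp(-2 * a_P * p$h))
}

#' Upward attenuation through the palisade layer
#'
#' Mirror of [palisade_forward()] for the backward flows, plus the
#' backscatter source `js_add` gained by the upward scattered flow at the
#' top of the layer.
#'
#' @param J_C_h,J_S_h Backward collimated and scattered flux at the bottom
#'   of the layer.
#' @param p [palisade_params()].
#' @param a_P Absorption coefficient, cm^-1.
#' @param beta_I2 Internal propagation angle of the backward collimated
#'   flow, rad.
#' @param js_add Backscatter source from the downward flows (see
#'   [js_add()]); added to the scattered flow after attenuation.
#' @return List with `J_C0` and `J_S0`, fluxes at the top of the layer.
#' @export
palisade_backward <- function(J_C_h, J_S_h, p, a_P, beta_I2, js_add = 0) {
  if (cos(beta_I2) <= 1e-9) stop("grazing internal angle: degenerate path")
  if (any(J_C_h < 0) || any(J_S_h < 0)) stop("fluxes must be >= 0")
  list(J_C0 = J_C_h * exp(-a_P * p$h / cos(beta_I2)),
       J_S0 = J_S_h * exp(-2 * a_P * p$h) + js_add)
}

#' Backscatter source of the palisade layer
#'
#' Closed form of the depth integral of single backscattering from the two
#' downward flows: light scattered out of `I_C` (slant path) and `I_S`
#' (path factor 2) into the backward hemisphere (weight `1 - f`), attenuated
#' back up to the top of the layer:
#' \deqn{J_S^{Add} = I_C(0)\,\frac{s_P(1-f)}{a_P(1+2\cos\beta_{I1})}
#'   \left(1 - e^{-(a_P/\cos\beta_{I1} + 2 a_P)h}\right)
#'   + I_S(0)\,\frac{s_P(1-f)}{2 a_P}\left(1 - e^{-4 a_P h}\right).}
#' For `a_P` below 1e-9 cm^-1 the analytic zero-absorption limit
#' `I_C(0) s_P (1-f) h / cos(beta_I1) + 2 I_S(0) s_P (1-f) h` is used (the
#' printed form divides by `a_P`); this matters at near-infrared
#' wavelengths where pigment absorption vanishes.
#'
#' @inheritParams palisade_forward
#' @return Added backward scattered intensity at the top of the layer.
#' @export
js_add <- function(I_C0, I_S0, p, a_P, beta_I1) {
  if (any(I_C0 < 0) || any(I_S0 < 0) || any(a_P < 0))
    stop("fluxes and absorption must be >= 0")
  cb <- cos(beta_I1)
  sp1f <- p$s_P * (1 - p$f)
  n <- max(length(I_C0), length(I_S0), length(a_P))
  a <- rep_len(a_P, n)
  ic <- rep_len(I_C0, n)
  is_ <- rep_len(I_S0, n)
  out <- numeric(n)
  tiny <- a < 1e-9
  if (any(!tiny)) {
    aa <- a[!tiny]
    t1 <- ic[!tiny] * sp1f / (aa * (1 + 2 * cb)) *
      (1 - exp(-(aa / cb + 2 * aa) * p$h))
    t2 <- is_[!tiny] * sp1f / (2 * aa) * (1 - exp(-4 * aa * p$h))
    out[!tiny] <- t1 + t2
  }
  if (any(tiny))
    out[tiny] <- ic[tiny] * sp1f * p$h / cb + 2 * is_[tiny] * sp1f * p$h
  out
}
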