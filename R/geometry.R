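# Boundary optics at the air-leaf and leaf-air interfaces: Snell refraction,
# unpolarized Fresnel transmittance of collimated beams, hemispherically
# averaged transmittance of diffuse light, and the partition of incident /
# exiting light between smooth and rough surface fractions.

# cache of hemispherical transmittances, keyed by "n_O:n_I:direction"
.hemi_cache <- new.env(parent = emptyenv())

#' Refraction angle from Snell's law
#'
#' Computes the internal propagation angle for a collimated beam entering an
#' optically denser medium (air to leaf interior).
#'
#' @param beta_O External incidence angle in radians, in `[0, pi/2]`.
#' @param n_O Refractive index of the outer medium (air), default 1.
#' @param n_I Refractive index of the leaf interior, default 1.415.
#' @return Internal angle in radians. Always below the critical angle
#'   `asin(n_O/n_I)` for `n_I > n_O`.
#' @examples
#' refract(35 * pi / 180)            # ~ 23.9 degrees
#' refract(pi / 2) * 180 / pi        # the critical angle, ~ 45 degrees
#' @export
refract <- function(beta_O, n_O = 1, n_I = 1.415) {
  stopifnot(n_I >= n_O, n_O > 0)
  if (any(beta_O < 0 | beta_O > pi / 2 + 1e-12))
    stop("incidence angle must lie in [0, pi/2] radians")
  asin(pmin(1, (n_O / n_I) * sin(beta_O)))
}

#' Critical angle for total internal reflection
#'
#' @inheritParams refract
#' @return Internal angle in radians above which light cannot exit the leaf.
#' @export
critical_angle <- function(n_O = 1, n_I = 1.415) {
  stopifnot(n_I > n_O)
  asin(n_O / n_I)
}

#' Unpolarized Fresnel transmittance of a collimated beam
#'
#' Transmittance across a planar dielectric interface, averaged over s- and
#' p-polarization:
#' `1 - 1/2 * ((sin(d)/sin(s))^2 + (tan(d)/tan(s))^2)` with
#' `d = beta_in - beta_out`, `s = beta_in + beta_out`. The expression is
#' symmetric in its two angles, so the same value serves both directions of
#' travel (reciprocity below the critical angle). At normal incidence the
#' 0/0 form is replaced by the analytic limit
#' `1 - ((n_I - n_O)/(n_I + n_O))^2`. For travel from the dense medium at or
#' above the critical angle the beam is totally internally reflected and the
#' transmittance is 0.
#'
#' @param beta_in Propagation angle in the incidence medium (radians). May be
#'   a vector.
#' @param beta_out Refraction angle in the exit medium (radians); when `NULL`
#'   it is derived from Snell's law using `n_in` and `n_out`.
#' @param n_in,n_out Refractive indices of the incidence and exit media.
#' @return Transmitted fraction in `[0, 1]`.
#' @export
fresnel_transmittance <- function(beta_in, beta_out = NULL,
                                  n_in = 1, n_out = 1.415) {
  if (any(beta_in < 0 | beta_in > pi / 2 + 1e-12))
    stop("incidence angle must lie in [0, pi/2] radians")
  dense_to_rare <- n_in > n_out
  if (is.null(beta_out)) {
    s <- pmin(1, (n_in / n_out) * sin(beta_in))
    beta_out <- asin(s)
  }
  d <- beta_in - beta_out
  s <- beta_in + beta_out
  tt <- 1 - 0.5 * ((sin(d) / sin(s))^2 + (tan(d) / tan(s))^2)
  # analytic normal-incidence limit of the same expression
  t0 <- 1 - ((n_out - n_in) / (n_out + n_in))^2
  tt[abs(beta_in) < 1e-6] <- t0
  if (dense_to_rare) {
    bc <- asin(n_out / n_in)
    tt[beta_in >= bc - 1e-12] <- 0
  }
  pmin(pmax(tt, 0), 1)
}

#' Hemispherically averaged transmittance of diffuse light
#'
#' Equal-weight average of the collimated Fresnel transmittance over the
#' incidence angle, `(2/pi) * integral_0^{pi/2} T_c(beta) d beta`. The weight
#' is uniform in the angle itself (not cosine-weighted). For the leaf-to-air
#' direction the integrand is zero above the critical angle, so the integral
#' effectively runs to `asin(n_O/n_I)` only. Values are cached per index
#' pair; with the default indices the two directions evaluate to about 0.866
#' (air to leaf) and 0.469 (leaf to air).
#'
#' @param direction `"air_to_leaf"` or `"leaf_to_air"`.
#' @inheritParams refract
#' @return Diffuse transmittance fraction in `[0, 1]`.
#' @export
hemispherical_transmittance <- function(direction = c("air_to_leaf",
                                                      "leaf_to_air"),
                                        n_O = 1, n_I = 1.415) {
  direction <- match.arg(direction)
  if (n_I == n_O) return(1)
  stopifnot(n_I > n_O)
  key <- paste(format(n_O, digits = 15), format(n_I, digits = 15), direction,
               sep = ":")
  hit <- .hemi_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (direction == "air_to_leaf") {
    fn <- function(b) fresnel_transmittance(b, n_in = n_O, n_out = n_I)
    upper <- pi / 2
  } else {
    fn <- function(b) fresnel_transmittance(b, n_in = n_I, n_out = n_O)
    upper <- critical_angle(n_O, n_I)  # integrand identically 0 beyond
  }
  val <- (2 / pi) * stats::integrate(fn, 0, upper, rel.tol = 1e-9,
                                     subdivisions = 500L)$value
  .hemi_cache[[key]] <- val
  val
}

#' Optical geometry of the leaf boundaries
#'
#' Bundles refractive indices, external incidence angles, the derived
#' internal refraction angles and the rough-surface fraction.
#'
#' @param beta_O1,beta_O2 External incidence angles at the adaxial and
#'   abaxial surfaces, in radians. `beta_O2` defaults to `beta_O1` so the
#'   abaxial internal angle is defined even when no abaxial light is
#'   incident.
#' @param n_O,n_I Refractive indices of air and leaf interior.
#' @param F_S Fraction of the surface that is rough, in `[0, 1]`. Light
#'   meeting the rough fraction exchanges as diffuse light with the
#'   hemispherical transmittances; the smooth fraction uses collimated
#'   Fresnel coefficients.
#' @return An object of class `optical_geometry` with fields `n_O`, `n_I`,
#'   `beta_O1`, `beta_O2`, `beta_I1`, `beta_I2`, `F_S`.
#' @export
optical_geometry <- function(beta_O1 = 35 * pi / 180, beta_O2 = beta_O1,
                             n_O = 1, n_I = 1.415, F_S = 0) {
  stopifnot(F_S >= 0, F_S <= 1, n_I > n_O, n_O >= 1)
  g <- list(n_O = n_O, n_I = n_I,
            beta_O1 = beta_O1, beta_O2 = beta_O2,
            beta_I1 = refract(beta_O1, n_O, n_I),
            beta_I2 = refract(beta_O2, n_O, n_I),
            F_S = F_S)
  class(g) <- "optical_geometry"
  g
}

#' Surface transmittance coefficients for a geometry
#'
#' Evaluates the collimated air-to-leaf / leaf-to-air transmittances at both
#' surfaces and the two hemispherical diffuse transmittances. By reciprocity
#' the leaf-to-air collimated coefficients equal their air-to-leaf
#' counterparts for internal angles below the critical angle (which
#' refraction guarantees here).
#'
#' @param geom An [optical_geometry()].
#' @return List with `T_Ic_OI`, `T_Jc_OI`, `T_Ic_IO`, `T_Jc_IO`, `T_s_OI`,
#'   `T_s_IO`.
#' @export
surface_transmittances <- function(geom) {
  T1 <- fresnel_transmittance(geom$beta_O1, geom$beta_I1,
                              n_in = geom$n_O, n_out = geom$n_I)
  T2 <- fresnel_transmittance(geom$beta_O2, geom$beta_I2,
                              n_in = geom$n_O, n_out = geom$n_I)
  list(T_Ic_OI = T1, T_Jc_OI = T2,
       T_Ic_IO = T1, T_Jc_IO = T2,
       T_s_OI = hemispherical_transmittance("air_to_leaf", geom$n_O, geom$n_I),
       T_s_IO = hemispherical_transmittance("leaf_to_air", geom$n_O, geom$n_I))
}

#' Partition incident light at the leaf surfaces
#'
#' Splits the externally incident collimated beams `I_0` (adaxial) and `J_0`
#' (abaxial) into the fluxes entering the lamina and those reflected back to
#' air. The smooth fraction `1 - F_S` transmits collimated light with the
#' Fresnel coefficient; the rough fraction `F_S` converts the beam to
#' scattered light with the hemispherical coefficient. The four output terms
#' per beam sum to the incident intensity exactly.
#'
#' @param I_0,J_0 Incident intensities at the adaxial and abaxial surfaces
#'   (nonnegative, any radiometric unit).
#' @param geom An [optical_geometry()].
#' @param trans Optional precomputed [surface_transmittances()].
#' @return List with components `entering` (`I_C0`, `I_S0`, `JC_hl`,
#'   `JS_hl`: fluxes just inside the lamina) and `reflected_to_air`
#'   (`J_C_RO`, `J_S_RO`, `I_C_RO`, `I_S_RO`).
#' @export
surface_in <- function(I_0, J_0, geom, trans = surface_transmittances(geom)) {
  if (any(I_0 < 0) || any(J_0 < 0)) stop("incident intensities must be >= 0")
  F_S <- geom$F_S
  list(
    entering = list(
      I_C0  = I_0 * (1 - F_S) * trans$T_Ic_OI,
      I_S0  = I_0 * F_S * trans$T_s_OI,
      JC_hl = J_0 * (1 - F_S) * trans$T_Jc_OI,
      JS_hl = J_0 * F_S * trans$T_s_OI),
    reflected_to_air = list(
      J_C_RO = I_0 * (1 - F_S) * (1 - trans$T_Ic_OI),
      J_S_RO = I_0 * F_S * (1 - trans$T_s_OI),
      I_C_RO = J_0 * (1 - F_S) * (1 - trans$T_Jc_OI),
      I_S_RO = J_0 * F_S * (1 - trans$T_s_OI)))
}

#' Partition outgoing internal light at the leaf surfaces
#'
#' Takes the four internal fluxes arriving at the boundaries - backward
#' collimated `J_C(0)` and backward scattered `J_S(0)` at the adaxial
#' surface, forward collimated `I_C(h+l)` and forward scattered `I_S(h+l)`
#' at the abaxial surface - and splits each into the part transmitted to air
#' and the part reflected back into the lamina. Collimated light hitting the
#' rough fraction exits (or reflects) as scattered light with the
#' hemispherical coefficient; the smooth fraction keeps it collimated with
#' the Fresnel coefficient of the flow's propagation angle.
#'
#' @param J_C0,J_S0 Upward collimated / scattered flux at the top of the
#'   palisade layer.
#' @param IC_hl,IS_hl Downward collimated / scattered flux at the bottom of
#'   the spongy layer.
#' @inheritParams surface_in
#' @return List with components `transmitted` (`J_C_T`, `J_S_T`, `I_C_T`,
#'   `I_S_T`) and `reflected_internally` (`I_C_RI`, `I_S_RI`, `J_C_RI`,
#'   `J_S_RI`).
#' @export
surface_out <- function(J_C0, J_S0, IC_hl, IS_hl, geom,
                        trans = surface_transmittances(geom)) {
  F_S <- geom$F_S
  list(
    transmitted = list(
      J_C_T = J_C0 * (1 - F_S) * trans$T_Jc_IO,
      J_S_T = J_C0 * F_S * trans$T_s_IO + J_S0 * trans$T_s_IO,
      I_C_T = IC_hl * (1 - F_S) * trans$T_Ic_IO,
      I_S_T = IC_hl * F_S * trans$T_s_IO + IS_hl * trans$T_s_IO),
    reflected_internally = list(
      I_C_RI = J_C0 * (1 - F_S) * (1 - trans$T_Jc_IO),
      I_S_RI = J_C0 * F_S * (1 - trans$T_s_IO) + J_S0 * (1 - trans$T_s_IO),
      J_C_RI = IC_hl * (1 - F_S) * (1 - trans$T_Ic_IO),
      J_S_RI = IC_hl * F_S * (1 - trans$T_s_IO) + IS_hl * (1 - trans$T_s_IO)))
}

#' Total light leaving the leaf in one iteration
#'
#' Sums the per-surface exit components into the adaxial (`J_out_i`) and
#' abaxial (`I_out_i`) outputs of one iteration. External reflection terms
#' (`*_RO`) arise from incident light only and therefore contribute on the
#' first iteration alone; pass `reflected_to_air = NULL` (the default) for
#' later iterations.
#'
#' @param transmitted `transmitted` component of a [surface_out()] result.
#' @param reflected_to_air Optional `reflected_to_air` component of a
#'   [surface_in()] result (first iteration only).
#' @return List with `J_out_i` and `I_out_i`.
#' @export
exit_totals <- function(transmitted, reflected_to_air = NULL) {
  J <- transmitted$J_C_T + transmitted$J_S_T
  I <- transmitted$I_C_T + transmitted$I_S_T
  if (!is.null(reflected_to_air)) {
    J <- J + reflected_to_air$J_C_RO + reflected_to_air$J_S_RO
    I <- I + reflected_to_air$I_C_RO + reflected_to_air$I_S_RO
  }
  list(J_out_i = J, I_out_i = I)
}

#' @export
print.optical_geometry <- function(x, ...) {
  cat("Leaf boundary geometry\n")
  cat(sprintf("  n_O = %.3f, n_I = %.3f (critical angle %.2f deg)\n",
              x$n_O, x$n_I, critical_angle(x$n_O, x$n_I) * 180 / pi))
  cat(sprintf("  beta_O1 = %.2f deg -> beta_I1 = %.2f deg\n",
              x$beta_O1 * 180 / pi, x$beta_I1 * 180 / pi))
  cat(sprintf("  beta_O2 = %.2f deg -> beta_I2 = %.2f deg\n",
              x$beta_O2 * 180 / pi, x$beta_I2 * 180 / pi))
  cat(sprintf("  rough-surface fraction F_S = %.3f\n", x$F_S))
  invisible(x)
}
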