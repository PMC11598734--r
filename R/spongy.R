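# Four-flux Kubelka-Munk radiative transfer in the spongy mesophyll. The
# collimated flows decay independently; the two scattered flows form a
# coupled linear 2x2 system fed by collimated scattering, solved in closed
# form by eigen-decomposition and matched to two-point boundary conditions
# (downward flows known at the top of the layer, upward flows at the
# bottom). All formulas are vectorized over the absorption coefficient so a
# whole wavelength grid is solved at once.

#' Spongy layer parameters
#'
#' @param l Layer thickness in cm.
#' @param a_Sp Absorption coefficient, cm^-1; scalar or vector (one per
#'   wavelength). Values are clamped to a floor of 1e-6 cm^-1: at exactly
#'   zero absorption the two scattered-flow eigenvalues coincide at 0 and
#'   the closed-form constants become singular. Outputs are continuous
#'   across the floor.
#' @param s_Sp Scattering coefficient, cm^-1. Default 600.
#' @param f Asymmetry factor shared with the palisade layer.
#' @return Object of class `spongy_params`.
#' @export
spongy_params <- function(l, a_Sp, s_Sp = 600, f = 0.5) {
  stopifnot(l >= 0, all(a_Sp >= 0), s_Sp >= 0, f >= 0, f <= 1)
  structure(list(l = l, a_Sp = pmax(a_Sp, 1e-6), s_Sp = s_Sp, f = f),
            class = "spongy_params")
}

#' Coefficient matrix of the four-flux system
#'
#' Maps the layer parameters and the two collimated propagation angles onto
#' the linear ODE coefficients `L11..L44` of the four-flux system: the
#' collimated flows lose `(a_Sp + s_Sp)` per unit slant path; scattered
#' gains split `f` forward / `1 - f` backward; the scattered flows use the
#' diffuse path-length factor 2.
#'
#' @param sp [spongy_params()].
#' @param beta_I1,beta_I2 Propagation angles of the forward and backward
#'   collimated flows, rad.
#' @return Object of class `km_matrix`: list of coefficient vectors plus
#'   the generating parameters.
#' @export
build_km_matrix <- function(sp, beta_I1, beta_I2) {
  c1 <- cos(beta_I1); c2 <- cos(beta_I2)
  if (c1 <= 1e-9 || c2 <= 1e-9) stop("grazing internal angle: degenerate path")
  a <- sp$a_Sp; s <- sp$s_Sp; f <- sp$f
  m <- list(
    L11 = -(a + s) / c1,
    L22 = +(a + s) / c2,
    L31 = f * s / c1,
    L32 = (1 - f) * s / c2,
    L33 = -2 * (a + s * (1 - f)),
    L34 = 2 * s * (1 - f),
    L41 = -(1 - f) * s / c1,
    L42 = -f * s / c2,
    L43 = -2 * s * (1 - f),
    L44 = +2 * (a + s * (1 - f)),
    a_Sp = a, s_Sp = s, f = f, beta_I1 = beta_I1, beta_I2 = beta_I2)
  class(m) <- "km_matrix"
  m
}

#' Eigenvalues of the four-flux system
#'
#' The collimated eigenvalues are the decoupled decay rates `L11` and
#' `L22`. The scattered pair are the roots of the characteristic quadratic
#' of the 2x2 scattered block, `lambda^2 - (L33 + L44) lambda +
#' (L33 L44 - L34 L43) = 0`; with the standard sign structure
#' (`L33 + L44 = 0`) this reduces to the classical Kubelka-Munk exponent
#' `lambda3 = -lambda4 = 2 sqrt(a_Sp (a_Sp + 2 s_Sp (1 - f)))`.
#'
#' @param m A [build_km_matrix()] result.
#' @return List of vectors `lambda1..lambda4`, with `lambda3 >= lambda4`.
#' @export
km_eigenvalues <- function(m) {
  tr <- m$L33 + m$L44
  dt <- m$L33 * m$L44 - m$L34 * m$L43
  disc <- tr^2 / 4 - dt
  if (any(disc < 0))
    stop("complex scattered-flow eigenvalues: non-physical parameters")
  r <- sqrt(disc)
  list(lambda1 = m$L11, lambda2 = m$L22,
       lambda3 = tr / 2 + r, lambda4 = tr / 2 - r)
}

#' Solve the spongy layer for given boundary fluxes
#'
#' Matches the analytic solution to the two-point boundary conditions:
#' downward flows `I_C(h)`, `I_S(h)` prescribed at the top of the layer,
#' upward flows `J_C(h+l)`, `J_S(h+l)` at the bottom. Particular constants
#' attached to the collimated exponentials and homogeneous constants of the
#' scattered block are computed in a rescaled form (growing exponentials
#' are anchored at the boundary where they are largest) so optically thick
#' layers evaluate without overflow.
#'
#' Near-degenerate resonances, where a collimated decay rate coincides with
#' a scattered-block eigenvalue and the particular-solution denominator
#' vanishes, are handled by nudging the affected absorption values by one
#' part in 1e5 (a removable singularity of the closed form; the nudge is
#' far below parameter uncertainty).
#'
#' @param IC_h,IS_h Downward collimated / scattered flux at the top of the
#'   layer.
#' @param JC_hl,JS_hl Upward collimated / scattered flux at the bottom.
#' @param sp [spongy_params()].
#' @param m Optional [build_km_matrix()]; rebuilt from `sp` and the angles
#'   stored in `m` when a resonance nudge is required.
#' @param h Depth of the top of the layer (cm); evaluation coordinates are
#'   absolute depths in `[h, h + l]`.
#' @return Object of class `km_solution` for [km_evaluate()].
#' @export
km_solve <- function(IC_h, IS_h, JC_hl, JS_hl, sp, m, h = 0) {
  if (any(IC_h < 0) || any(IS_h < 0) || any(JC_hl < 0) || any(JS_hl < 0))
    stop("boundary fluxes must be >= 0")
  l <- sp$l
  a <- m$a_Sp
  # resolve collimated/scattered eigenvalue resonances by a tiny nudge
  for (k in 1:5) {
    ev <- km_eigenvalues(m)
    scale <- (abs(ev$lambda1) + abs(ev$lambda2) + ev$lambda3 + 1)^2
    den1 <- (ev$lambda1 - ev$lambda3) * (ev$lambda1 - ev$lambda4)
    den2 <- (ev$lambda2 - ev$lambda3) * (ev$lambda2 - ev$lambda4)
    bad <- abs(den1) < 1e-7 * scale | abs(den2) < 1e-7 * scale
    if (!any(bad)) break
    a[bad] <- a[bad] * (1 + 1e-5) + 1e-9
    sp2 <- sp; sp2$a_Sp <- a
    m <- build_km_matrix(sp2, m$beta_I1, m$beta_I2)
  }
  l1 <- ev$lambda1; l2 <- ev$lambda2; l3 <- ev$lambda3; l4 <- ev$lambda4

  n <- max(length(IC_h), length(IS_h), length(JC_hl), length(JS_hl),
           length(a))
  IC_h <- rep_len(IC_h, n); IS_h <- rep_len(IS_h, n)
  JC_hl <- rep_len(JC_hl, n); JS_hl <- rep_len(JS_hl, n)

  # particular constants driven by the two collimated exponentials;
  # C2r/D2r absorb the e^{lambda2 l} anchor of the upward collimated flow
  C1  <- IC_h * (-m$L31 * (m$L44 - l1) + m$L41 * m$L34) / den1
  D1  <- IC_h * (-m$L41 * (m$L33 - l1) + m$L31 * m$L43) / den1
  C2r <- JC_hl * (-m$L32 * (m$L44 - l2) + m$L42 * m$L34) / den2
  D2r <- JC_hl * (-m$L42 * (m$L33 - l2) + m$L32 * m$L43) / den2

  E1 <- exp(l1 * l)            # decaying, <= 1
  rIS <- IS_h - C1 - C2r * exp(-l2 * l)       # scattered residual at top
  rJS <- JS_hl - D1 * E1 - D2r                # scattered residual at bottom

  if (m$L34[1] == 0 && m$s_Sp * (1 - m$f) == 0) {
    # scattered block is diagonal: IS rides e^{L33 x1}, JS rides e^{L44 x1}
    C3s <- rep_len(0, n); D4 <- rep_len(0, n)
    C4 <- rIS            # attached to e^{lambda4 (x - h)}, lambda4 = L33
    D3s <- rJS           # attached to e^{lambda3 (x - h - l)}, lambda3 = L44
  } else {
    E4 <- exp(l4 * l)          # decaying
    q  <- exp((l4 - l3) * l)   # e^{-2 lambda3 l}, may underflow to 0
    dn <- (m$L33 - l4) * q - (m$L33 - l3)     # rescaled denominator
    C3s <- (rIS * (m$L33 - l4) * E4 + rJS * m$L34) / dn
    C4  <- (-rJS * m$L34 * exp(-l3 * l) - rIS * (m$L33 - l3)) / dn
    D3s <- -C3s * (m$L33 - l3) / m$L34
    D4  <- -C4 * (m$L33 - l4) / m$L34
  }

  structure(list(lambda1 = l1, lambda2 = l2, lambda3 = l3, lambda4 = l4,
                 A1 = IC_h, JC_hl = JC_hl,
                 C1 = C1, D1 = D1, C2r = C2r, D2r = D2r,
                 C3s = C3s, C4 = C4, D3s = D3s, D4 = D4,
                 h = h, l = l),
            class = "km_solution")
}

#' Evaluate the spongy-layer flows at a depth
#'
#' @param sol A [km_solution][km_solve()].
#' @param x Absolute depth in cm, in `[h, h + l]`.
#' @return List of flux vectors `I_C`, `I_S`, `J_C`, `J_S` at depth `x`.
#' @export
km_evaluate <- function(sol, x) {
  x1 <- x - sol$h
  if (x1 < -1e-12 || x1 > sol$l + 1e-12)
    stop("depth outside the spongy layer")
  x1 <- min(max(x1, 0), sol$l)
  xb <- x1 - sol$l   # <= 0: anchors growing exponentials at the bottom
  e1 <- exp(sol$lambda1 * x1)
  e2 <- exp(sol$lambda2 * xb)
  e3 <- exp(sol$lambda3 * xb)
  e4 <- exp(sol$lambda4 * x1)
  list(
    I_C = sol$A1 * e1,
    J_C = sol$JC_hl * e2,
    I_S = sol$C1 * e1 + sol$C2r * e2 + sol$C3s * e3 + sol$C4 * e4,
    J_S = sol$D1 * e1 + sol$D2r * e2 + sol$D3s * e3 + sol$D4 * e4)
}
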