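# Orchestration of one full light pass (surface -> palisade -> spongy ->
# surface) and iteration of the internally reflected fluxes. Reflectance is
# the accumulated adaxial output over the incident intensity; transmittance
# the abaxial output. All per-wavelength quantities are vectors, so one call
# sweeps the whole spectrum.

#' Full model parameter set
#'
#' Collects every tunable parameter of the two-layer leaf model with the
#' parameterized pea-leaf defaults. Angles are given in degrees and
#' thicknesses in micrometres at this configuration boundary; internally
#' radians and centimetres are used throughout.
#'
#' @param beta_O1 External incidence angle at the adaxial surface, degrees.
#' @param beta_O2 External incidence angle at the abaxial surface, degrees;
#'   defaults to `beta_O1` so the abaxial internal angle is defined when
#'   only adaxial light is incident.
#' @param n_O,n_I Refractive indices of air and leaf interior.
#' @param F_S Rough-surface fraction in `[0, 1]`.
#' @param I_0,J_0 Incident collimated intensities at the adaxial and abaxial
#'   surfaces (umol m^-2 s^-1; any unit - results are ratios).
#' @param h,l Palisade and spongy mesophyll thicknesses, micrometres.
#' @param s_P,s_Sp Scattering coefficients of the two layers, cm^-1.
#' @param f Asymmetry factor shared by both layers.
#' @param C_ChA,C_ChB,C_Car Chlorophyll a, chlorophyll b and carotenoid
#'   concentrations in the palisade layer, mg cm^-3.
#' @param N_SpP Spongy/palisade pigment-concentration ratio.
#' @param N Number of internal-reflection iterations.
#' @param wavelengths Wavelength grid in nm for spectral simulation.
#' @return Object of class `leaf_params` with angles in radians and
#'   thicknesses in cm.
#' @export
leaf_params <- function(beta_O1 = 35, beta_O2 = beta_O1,
                        n_O = 1, n_I = 1.415, F_S = 0.15,
                        I_0 = 1000, J_0 = 0,
                        h = 35.5, l = 58.6,
                        s_P = 5, s_Sp = 600, f = 0.5,
                        C_ChA = 3.19, C_ChB = 2.09, C_Car = 0.94,
                        N_SpP = 0.2, N = 6,
                        wavelengths = 400:800) {
  stopifnot(I_0 >= 0, J_0 >= 0, h >= 0, l >= 0, s_P >= 0, s_Sp >= 0,
            f >= 0, f <= 1, C_ChA >= 0, C_ChB >= 0, C_Car >= 0,
            N_SpP >= 0, N_SpP <= 1, N >= 1,
            all(diff(wavelengths) > 0))
  p <- list(beta_O1 = beta_O1 * pi / 180, beta_O2 = beta_O2 * pi / 180,
            n_O = n_O, n_I = n_I, F_S = F_S,
            I_0 = I_0, J_0 = J_0,
            h = um_to_cm(h), l = um_to_cm(l),
            s_P = s_P, s_Sp = s_Sp, f = f,
            C_ChA = C_ChA, C_ChB = C_ChB, C_Car = C_Car,
            N_SpP = N_SpP, N = as.integer(N),
            wavelengths = wavelengths)
  class(p) <- "leaf_params"
  p
}

#' Update a parameter set with user-unit values
#'
#' Applies named replacements to a [leaf_params()] object using the same
#' units as the constructor (`beta_O1`/`beta_O2` in degrees, `h`/`l` in
#' micrometres, everything else as stored).
#'
#' @param params A [leaf_params()] object.
#' @param ... Named replacements.
#' @return The updated `leaf_params` object.
#' @export
update_leaf_params <- function(params, ...) {
  repl <- list(...)
  if (length(repl) == 0) return(params)
  nm <- names(repl)
  if (is.null(nm) || any(nm == "")) stop("replacements must be named")
  unknown <- setdiff(nm, names(params))
  if (length(unknown) > 0)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  for (k in nm) {
    v <- repl[[k]]
    if (k %in% c("beta_O1", "beta_O2")) v <- v * pi / 180
    if (k %in% c("h", "l")) v <- um_to_cm(v)
    params[[k]] <- v
  }
  params
}

#' @export
print.leaf_params <- function(x, ...) {
  cat("Two-layer leaf model parameters\n")
  cat(sprintf("  incidence: beta_O1 = %.1f deg, I_0 = %g, J_0 = %g\n",
              x$beta_O1 * 180 / pi, x$I_0, x$J_0))
  cat(sprintf("  surface:   n_I = %.3f, F_S = %.3f\n", x$n_I, x$F_S))
  cat(sprintf("  palisade:  h = %.1f um, s_P = %g cm-1\n",
              x$h * 1e4, x$s_P))
  cat(sprintf("  spongy:    l = %.1f um, s_Sp = %g cm-1, f = %.2f\n",
              x$l * 1e4, x$s_Sp, x$f))
  cat(sprintf("  pigments:  ChA %.2f, ChB %.2f, Car %.2f mg cm-3, N_Sp/P = %.2f\n",
              x$C_ChA, x$C_ChB, x$C_Car, x$N_SpP))
  cat(sprintf("  iterations N = %d, %d wavelengths\n",
              x$N, length(x$wavelengths)))
  invisible(x)
}

# one surface->palisade->spongy->surface pass; `state` carries the fluxes
# entering the lamina and the propagation angles of the two collimated
# flows (which swap between iterations because reflected flows reverse).
.one_pass <- function(state, params, pal, trans) {
  b1 <- state$beta1; b2 <- state$beta2
  Tf <- state$Tf;   Tb <- state$Tb       # collimated exit T at b1 / b2
  F_S <- params$F_S
  T_s_IO <- trans$T_s_IO

  down <- palisade_forward(state$I_C0, state$I_S0, pal, state$a_P, b1)
  jadd <- js_add(state$I_C0, state$I_S0, pal, state$a_P, b1)

  sp <- spongy_params(params$l, state$a_Sp, params$s_Sp, params$f)
  m <- build_km_matrix(sp, b1, b2)
  sol <- km_solve(down$I_C_h, down$I_S_h, state$JC_hl, state$JS_hl, sp, m,
                  h = params$h)
  top <- lapply(km_evaluate(sol, params$h), pmax, 0)          # clamp roundoff
  bot <- lapply(km_evaluate(sol, params$h + params$l), pmax, 0)

  up <- palisade_backward(top$J_C, top$J_S, pal, state$a_P, b2,
                          js_add = jadd)

  geom <- list(F_S = F_S)  # surface_out needs only F_S + transmittances
  tr_i <- list(T_Jc_IO = Tb, T_Ic_IO = Tf, T_s_IO = T_s_IO)
  ex <- surface_out(up$J_C0, up$J_S0, bot$I_C, bot$I_S, geom, tr_i)

  next_state <- list(
    I_C0 = ex$reflected_internally$I_C_RI,
    I_S0 = ex$reflected_internally$I_S_RI,
    JC_hl = ex$reflected_internally$J_C_RI,
    JS_hl = ex$reflected_internally$J_S_RI,
    a_P = state$a_P, a_Sp = state$a_Sp,
    beta1 = b2, beta2 = b1, Tf = Tb, Tb = Tf)  # reflected flows reverse

  list(transmitted = ex$transmitted, next_state = next_state)
}

#' Simulate reflectance and transmittance at fixed absorption
#'
#' Runs `N` iterations of light propagation for given palisade and spongy
#' absorption coefficients (scalars or per-wavelength vectors) and
#' accumulates the adaxial and abaxial exit totals. Iteration 1 partitions
#' the incident beams at the surfaces (including the externally reflected
#' part); every later iteration re-propagates the internally reflected
#' fluxes with the collimated propagation angles swapped.
#'
#' @param a_P Palisade absorption coefficient(s), cm^-1.
#' @param a_Sp Spongy absorption coefficient(s), cm^-1 (clamped to a 1e-6
#'   floor, see [spongy_params()]).
#' @param params [leaf_params()].
#' @param N Number of iterations; defaults to `params$N`.
#' @param keep_ledger If `TRUE`, per-iteration exit totals are returned.
#' @return List with `R` (reflectance `J_out / I_0`), `T` (transmittance
#'   `I_out / I_0`), the raw totals `J_out` and `I_out`, and optionally
#'   `ledger`, a list with per-iteration matrices `J_out_i`, `I_out_i`
#'   (iterations in rows). `R` and `T` are `NA` when `I_0 = 0`.
#' @export
simulate_monochromatic <- function(a_P, a_Sp, params, N = params$N,
                                   keep_ledger = FALSE) {
  stopifnot(N >= 1)
  n <- max(length(a_P), length(a_Sp))
  a_P <- rep_len(a_P, n)
  a_Sp <- pmax(rep_len(a_Sp, n), 1e-6)

  geom <- optical_geometry(params$beta_O1, params$beta_O2,
                           params$n_O, params$n_I, params$F_S)
  trans <- surface_transmittances(geom)
  pal <- palisade_params(params$h, params$s_P, params$f)

  inc <- surface_in(params$I_0, params$J_0, geom, trans)
  state <- list(I_C0 = rep_len(inc$entering$I_C0, n),
                I_S0 = rep_len(inc$entering$I_S0, n),
                JC_hl = rep_len(inc$entering$JC_hl, n),
                JS_hl = rep_len(inc$entering$JS_hl, n),
                a_P = a_P, a_Sp = a_Sp,
                beta1 = geom$beta_I1, beta2 = geom$beta_I2,
                Tf = trans$T_Ic_OI, Tb = trans$T_Jc_OI)

  J_out <- numeric(n); I_out <- numeric(n)
  ledger_J <- if (keep_ledger) matrix(0, N, n) else NULL
  ledger_I <- if (keep_ledger) matrix(0, N, n) else NULL

  for (i in seq_len(N)) {
    pass <- .one_pass(state, params, pal, trans)
    tot <- exit_totals(pass$transmitted,
                       if (i == 1) inc$reflected_to_air else NULL)
    J_out <- J_out + tot$J_out_i
    I_out <- I_out + tot$I_out_i
    if (keep_ledger) {
      ledger_J[i, ] <- tot$J_out_i
      ledger_I[i, ] <- tot$I_out_i
    }
    state <- pass$next_state
  }

  denom <- params$I_0
  out <- list(R = if (denom > 0) J_out / denom else rep(NA_real_, n),
              T = if (denom > 0) I_out / denom else rep(NA_real_, n),
              J_out = J_out, I_out = I_out)
  if (keep_ledger) out$ledger <- list(J_out_i = ledger_J, I_out_i = ledger_I)
  out
}

#' Simulate a full reflectance/transmittance spectrum
#'
#' Builds per-wavelength absorption coefficients from the pigment
#' concentrations and specific absorption spectra, then runs
#' [simulate_monochromatic()] across the wavelength grid.
#'
#' @param params [leaf_params()].
#' @param spectra Specific absorption spectra from [fixture_spectra()] or
#'   [read_pigment_csv()]; interpolated onto `params$wavelengths`.
#' @param N Number of iterations; defaults to `params$N`.
#' @return A `leaf_spectrum` data frame with columns `wavelength`,
#'   `reflectance`, `transmittance`, `absorptance`.
#' @export
simulate_spectrum <- function(params, spectra = fixture_spectra(),
                              N = params$N) {
  wl <- params$wavelengths
  a_P <- palisade_absorption(params, spectra, wl)
  a_Sp <- spongy_absorption(a_P, params$N_SpP)
  sim <- simulate_monochromatic(a_P, a_Sp, params, N = N)
  leaf_spectrum(wl, sim$R, sim$T)
}

#' Construct a spectrum object
#'
#' @param wavelength Strictly increasing wavelength grid, nm.
#' @param reflectance,transmittance Per-wavelength fractions.
#' @return Data frame of class `leaf_spectrum` with an `absorptance` column
#'   `1 - R - T`.
#' @export
leaf_spectrum <- function(wavelength, reflectance, transmittance = NA_real_) {
  stopifnot(all(diff(wavelength) > 0))
  s <- data.frame(wavelength = wavelength,
                  reflectance = reflectance,
                  transmittance = transmittance,
                  absorptance = 1 - reflectance - transmittance)
  class(s) <- c("leaf_spectrum", "data.frame")
  s
}
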