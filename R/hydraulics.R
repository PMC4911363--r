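#' Irradiance-dependent component of xylem hydraulic conductance
#'
#' `a + b * min(ppfd / ppfd_lim, 1)`: conductance rises linearly with light
#' and saturates at the limiting PPFD.
#'
#' @param ppfd incident PPFD, umol photon m-2 s-1 (vectorised).
#' @param params a [leaf_params()] object.
#' @return Conductance in g H2O m-2 s-1 MPa-1.
#' @export
kx_radiation <- function(ppfd, params = leaf_params()) {
  p <- as_leaf_params(params)
  if (any(ppfd < 0)) stop("ppfd must be non-negative", call. = FALSE)
  p$a + p$b * pmin(ppfd / p$ppfd_lim, 1)
}

#' Circadian oscillation component of xylem hydraulic conductance
#'
#' `tau_c * cos(-pi * t_osc / 60 + 5 * pi / 2) * (psi_x - psi_m_r)` where
#' `t_osc` is clock time expressed in the configured oscillation unit
#' (`osc_time_unit`, minutes by default, giving a 120-minute cycle). The
#' potential difference uses the constant reference potential `psi_m_r`, not
#' the instantaneous mesophyll potential.
#'
#' @param t time in seconds since midnight (vectorised).
#' @inheritParams kx_radiation
#' @return Conductance in g H2O m-2 s-1 MPa-1 (may be negative; the total
#'   conductance is floored at zero in [hydraulic_conductance()]).
#' @export
kx_oscillation <- function(t, params = leaf_params()) {
  p <- as_leaf_params(params)
  t_osc <- t / switch(p$osc_time_unit, minutes = 60, hours = 3600)
  p$tau_c * cos(-pi * t_osc / 60 + 5 * pi / 2) * (p$psi_x - p$psi_m_r)
}

#' Total xylem-to-mesophyll hydraulic conductance
#'
#' Sum of the irradiance and oscillation components, converted from
#' gravimetric to molar units by `cv_f1` and floored at zero (a negative
#' total conductance is physically meaningless and can arise from the
#' oscillation term at low light).
#'
#' @inheritParams kx_oscillation
#' @param ppfd incident PPFD, umol photon m-2 s-1.
#' @return Conductance in mol H2O m-2 s-1 MPa-1.
#' @export
hydraulic_conductance <- function(t, ppfd, params = leaf_params()) {
  p <- as_leaf_params(params)
  pmax(p$cv_f1 * (kx_radiation(ppfd, p) + kx_oscillation(t, p)), 0)
}

#' Osmotic potential of the mesophyll
#'
#' Van 't Hoff relation `-cv_f2 * R * Tl * Nm / Wm`.
#'
#' @param nm amount of dissolved solutes, mol m-2.
#' @param wm mesophyll water content, mol H2O m-2; must be positive.
#' @param tl leaf temperature, K.
#' @inheritParams kx_radiation
#' @return Osmotic potential in MPa (<= 0 for nm >= 0).
#' @export
osmotic_potential <- function(nm, wm, tl, params = leaf_params()) {
  p <- as_leaf_params(params)
  if (any(wm <= 0))
    stop("mesophyll water content must be positive", call. = FALSE)
  -p$cv_f2 * p$R * tl * nm / wm
}

#' Turgor (hydrostatic) pressure of the mesophyll
#'
#' Exponential pressure-volume approximation
#' `alpha * exp(-beta * (1 - Wm / Wm_max))`: equals the full turgor `alpha`
#' at complete hydration and decays with relative water deficit at a rate
#' set by the elasticity `beta`.
#'
#' @inheritParams osmotic_potential
#' @return Turgor pressure in MPa (> 0).
#' @export
turgor_pressure <- function(wm, params = leaf_params()) {
  p <- as_leaf_params(params)
  if (any(wm <= 0 | wm > p$wm_max))
    stop("water content must lie in (0, wm_max]", call. = FALSE)
  p$alpha * exp(-p$beta * (1 - wm / p$wm_max))
}

#' Mesophyll water potential and its components
#'
#' @inheritParams osmotic_potential
#' @return A list with `psi_s` (osmotic), `psi_p` (turgor) and their sum
#'   `psi_m`, all in MPa.
#' @export
mesophyll_potential <- function(nm, wm, tl, params = leaf_params()) {
  p <- as_leaf_params(params)
  psi_s <- osmotic_potential(nm, wm, tl, p)
  psi_p <- turgor_pressure(wm, p)
  list(psi_s = psi_s, psi_p = psi_p, psi_m = psi_s + psi_p)
}

#' Water influx from the xylem into the mesophyll
#'
#' `kx * (psi_x - psi_m)`: water flows in while the mesophyll is at lower
#' potential than the xylem.
#'
#' @param kx hydraulic conductance, mol H2O m-2 s-1 MPa-1 (>= 0).
#' @param psi_m mesophyll water potential, MPa.
#' @inheritParams kx_radiation
#' @return Influx in mol H2O m-2 s-1 (negative when water flows out).
#' @export
water_influx <- function(kx, psi_m, params = leaf_params()) {
  p <- as_leaf_params(params)
  if (any(kx < 0)) stop("hydraulic conductance must be >= 0", call. = FALSE)
  kx * (p$psi_x - psi_m)
}

#' Time derivatives of the mesophyll water and solute state
#'
#' Water balance `dWm/dt = Fi - Fo` and solute balance
#' `dNm/dt = c_i * n_xy * Fi`: solutes arrive dissolved in the xylem influx,
#' scaled by the ion exchange factor, and do not leave with transpiration.
#'
#' @param fi water influx, mol H2O m-2 s-1.
#' @param fo water efflux (transpiration), mol H2O m-2 s-1.
#' @inheritParams kx_radiation
#' @return A list with `dwm` and `dnm` (per-second derivatives).
#' @export
water_state_derivatives <- function(fi, fo, params = leaf_params()) {
  p <- as_leaf_params(params)
  list(dwm = fi - fo, dnm = p$c_i * p$n_xy * fi)
}
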