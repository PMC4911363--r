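#' Model parameters for the coupled leaf gas-exchange model
#'
#' Builds the full parameter set of the model with defaults for a fully
#' expanded, well-watered cucumber leaf. Parameters are grouped conceptually
#' into hydraulics (water transport and potentials), aerodynamics / energy
#' balance, stomata, and photosynthesis, but stored flat so any value can be
#' overridden by name.
#'
#' @param ... named overrides of any default, e.g. `leaf_params(gm = 0.6)`.
#'
#' @details
#' Hydraulics: `a`, `b` (g H2O m-2 s-1 MPa-1) and `ppfd_lim` (umol m-2 s-1)
#' shape the irradiance-dependent component of xylem hydraulic conductance;
#' `tau_c` (g H2O m-2 s-1 MPa-2) scales its circadian oscillation, evaluated
#' against the constant reference potential `psi_m_r` (MPa) and the xylem
#' potential `psi_x` (MPa). `cv_f1` (mol g-1) converts gravimetric to molar
#' conductance and `cv_f2` (mol L-1) litres of water to moles in the osmotic
#' term; `R` is the gas constant in L MPa mol-1 K-1. `n_xy` is the xylem sap
#' solute concentration (mol solute per mol H2O) and `c_i` the ion exchange
#' factor entering the solute balance. `alpha` (MPa, full turgor) and `beta`
#' (elasticity) define the pressure-volume curve, with `wm_max` (mol H2O m-2)
#' the water content at full hydration. `c_e` (Na+ exclusion coefficient) is
#' carried for completeness but enters no model equation.
#'
#' Aerodynamics: `gbw` is the boundary-layer conductance to water vapour
#' (mol m-2 s-1); `rho_a` (g mol-1) and `cp` (J g-1 K-1) give the molar heat
#' capacity of air; `gamma` the psychrometric constant (kPa K-1); `lam` the
#' molar latent heat of vaporisation (J mol-1); `a1` (kPa), `a2`, `a3` (K) the
#' saturation vapour-pressure constants; `g_i` the soil heat flux (J m-2 s-1,
#' zero for a single leaf); `k_rad` (J umol-1) converts PPFD to net radiation.
#'
#' Stomata: `g0` (mol CO2 m-2 s-1) and `g1` are the intercept and slope of the
#' steady-state target conductance; `alpha_g` (s-1) the kinetic time constant
#' and `r0` (mol H2O m-2 s-1) the initial lag conductance; `sf` (MPa-1) and
#' `psi_r` (MPa) govern the water-potential down-regulation of the target.
#'
#' Photosynthesis: `vcmax`, `jmax`, `theta`, `kappa2_ll`, `gamma_star`
#' (umol mol-1), `km` (umol mol-1), `rd`, `gm`, `ca` are the usual FvCB and
#' mesophyll-conductance constants held fixed over a day.
#'
#' Numerical switches: `de_min` (kPa) floors the vapour pressure deficit in the
#' stomatal target to avoid the 1/sqrt singularity at saturation;
#' `osc_time_unit` ("minutes" or "hours") sets the time unit of the hydraulic
#' oscillation argument; `slope_mode` ("literal" or "saturation") selects
#' whether the vapour-pressure slope is proportional to the deficit (literal
#' model form) or to the saturation pressure (thermodynamic convention);
#' `subtract_rd` subtracts day respiration `rd` from reported assimilation.
#'
#' @return An object of class `leaf_params`: a named list of all parameters.
#' @examples
#' p <- leaf_params()
#' p$gm
#' p2 <- leaf_params(gm = 0.8, g1 = 4.2)
#' @export
leaf_params <- function(...) {
  p <- list(
    # hydraulics
    a = 0.0259, b = 0.2268, ppfd_lim = 1000, tau_c = 0.324 / 15,
    psi_x = -0.08, psi_m_r = -0.9,
    cv_f1 = 0.05556, cv_f2 = 55.56, R = 8.3145e-3,
    n_xy = 0.0003, c_i = 2, c_e = 0.2,
    alpha = 2.4, beta = 10.6, wm_max = 16,
    # aerodynamics / energy balance
    gbw = 2.7, rho_a = 28.9645, cp = 1.012, gamma = 0.0665, lam = 44172,
    a1 = 0.61375, a2 = 17.502, a3 = 240.97, g_i = 0, k_rad = 0.4376,
    # stomata
    g0 = 0.009, g1 = 3.51, alpha_g = 4.0516e-3, r0 = 2.674e-3,
    sf = 4.9, psi_r = -0.9,
    # photosynthesis
    vcmax = 102, jmax = 140, theta = 0.75, kappa2_ll = 0.425,
    gamma_star = 43.02, km = 711, rd = 1.08, gm = 0.3, ca = 380,
    # numerical switches
    de_min = 0.01, osc_time_unit = "minutes", slope_mode = "literal",
    subtract_rd = FALSE
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("all parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(over)] <- over
  }
  validate_leaf_params(p)
  structure(p, class = "leaf_params")
}

validate_leaf_params <- function(p) {
  num_pos <- c("ppfd_lim", "cv_f1", "cv_f2", "R", "c_i", "beta", "wm_max",
               "gbw", "rho_a", "cp", "gamma", "lam", "a1", "a2", "a3",
               "alpha_g", "sf", "vcmax", "jmax", "kappa2_ll", "gamma_star",
               "km", "gm", "ca", "de_min")
  for (nm in num_pos)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a single positive number",
           call. = FALSE)
  num_nonneg <- c("a", "b", "tau_c", "n_xy", "g0", "r0", "g_i", "k_rad", "rd")
  for (nm in num_nonneg)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] < 0)
      stop("parameter '", nm, "' must be a single non-negative number",
           call. = FALSE)
  if (p$theta <= 0 || p$theta >= 1)
    stop("parameter 'theta' must lie strictly in (0, 1)", call. = FALSE)
  if (p$alpha <= 0) stop("parameter 'alpha' must be positive", call. = FALSE)
  if (!p$osc_time_unit %in% c("minutes", "hours"))
    stop("'osc_time_unit' must be \"minutes\" or \"hours\"", call. = FALSE)
  if (!p$slope_mode %in% c("literal", "saturation"))
    stop("'slope_mode' must be \"literal\" or \"saturation\"", call. = FALSE)
  if (!is.logical(p$subtract_rd) || length(p$subtract_rd) != 1L)
    stop("'subtract_rd' must be TRUE or FALSE", call. = FALSE)
  invisible(p)
}

#' @export
print.leaf_params <- function(x, ...) {
  cat("Leaf gas-exchange model parameters\n")
  grp <- list(
    hydraulics = c("a", "b", "ppfd_lim", "tau_c", "psi_x", "psi_m_r",
                   "cv_f1", "cv_f2", "R", "n_xy", "c_i", "c_e",
                   "alpha", "beta", "wm_max"),
    aerodynamics = c("gbw", "rho_a", "cp", "gamma", "lam",
                     "a1", "a2", "a3", "g_i", "k_rad"),
    stomata = c("g0", "g1", "alpha_g", "r0", "sf", "psi_r"),
    photosynthesis = c("vcmax", "jmax", "theta", "kappa2_ll", "gamma_star",
                       "km", "rd", "gm", "ca"),
    numerics = c("de_min", "osc_time_unit", "slope_mode", "subtract_rd")
  )
  for (g in names(grp)) {
    cat(" ", g, ":\n", sep = "")
    v <- unlist(lapply(x[grp[[g]]], format))
    cat(paste0("    ", format(names(v)), " = ", v), sep = "\n")
  }
  invisible(x)
}

as_leaf_params <- function(p) {
  if (inherits(p, "leaf_params")) return(p)
  if (is.list(p)) return(do.call(leaf_params, p))
  stop("'params' must be a leaf_params object or a named list", call. = FALSE)
}
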