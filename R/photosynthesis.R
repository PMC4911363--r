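#' Electron transport rate from incident light
#'
#' Non-rectangular hyperbola (smaller root):
#' `J = (k2ll*I + Jmax - sqrt((k2ll*I + Jmax)^2 - 4*theta*k2ll*I*Jmax)) /
#' (2*theta)`. Zero in darkness and saturating at `Jmax`.
#'
#' @param iinc incident PPFD, umol photon m-2 s-1 (vectorised).
#' @param params a [leaf_params()] object.
#' @return Electron transport rate in umol e- m-2 s-1.
#' @export
electron_transport <- function(iinc, params = leaf_params()) {
  p <- as_leaf_params(params)
  if (any(iinc < 0)) stop("iinc must be non-negative", call. = FALSE)
  x <- p$kappa2_ll * iinc
  b <- x + p$jmax
  (b - sqrt(pmax(b^2 - 4 * p$theta * x * p$jmax, 0))) / (2 * p$theta)
}

#' Chloroplastic CO2 mole fraction implied by an assimilation rate
#'
#' Diffusion drawdown through the stomatal and mesophyll conductances in
#' series: `Cc = Ca - A * (G + gm) / (G * gm)`.
#'
#' @param a net assimilation rate, umol CO2 m-2 s-1.
#' @param g stomatal conductance to CO2, mol m-2 s-1 (> 0).
#' @inheritParams electron_transport
#' @return Chloroplastic CO2 in umol mol-1.
#' @export
cc_from_a <- function(a, g, params = leaf_params()) {
  p <- as_leaf_params(params)
  p$ca - a * (g + p$gm) / (g * p$gm)
}

#' Cubic coefficients of the Rubisco-limited steady state
#'
#' Eliminating the chloroplastic CO2 and the target conductance from the
#' Rubisco-limited rate equation yields a cubic
#' `c3*A^3 + c2*A^2 + c1*A + c0 = 0` with
#' `c3 = gscb`, `c2 = g0m - gscb*Vcmax - gscb*gm*p2`,
#' `c1 = gm*p1*Vcmax*gscb - g0m*Vcmax - g0*gm*p2`,
#' `c0 = g0*gm*p1*Vcmax`, where `g0m = g0 + gm`, `p1 = Ca - Gamma*`,
#' `p2 = Ca + Km`.
#'
#' @param gscb slope of the steady-state target, see [target_coefficient()].
#' @inheritParams electron_transport
#' @return Numeric vector `c(c3, c2, c1, c0)`.
#' @export
cubic_rubisco <- function(gscb, params = leaf_params()) {
  p <- as_leaf_params(params)
  p1 <- p$ca - p$gamma_star
  p2 <- p$ca + p$km
  g0m <- p$g0 + p$gm
  c(gscb,
    g0m - gscb * p$vcmax - gscb * p$gm * p2,
    p$gm * p1 * p$vcmax * gscb - g0m * p$vcmax - p$g0 * p$gm * p2,
    p$g0 * p$gm * p1 * p$vcmax)
}

#' Cubic coefficients of the RuBP-regeneration-limited steady state
#'
#' Analogous elimination for the light-limited branch gives
#' `b3 = 4*gscb`, `b2 = 4*g0m - J*gscb - 4*k2*gm*gscb`,
#' `b1 = k1*gm*J*gscb - 4*k2*gm*g0 - J*g0m`, `b0 = k1*gm*J*g0`, with
#' `k1 = Ca - Gamma*` and `k2 = Ca + 2*Gamma*`.
#'
#' @inheritParams cubic_rubisco
#' @param j electron transport rate, umol e- m-2 s-1 (>= 0).
#' @return Numeric vector `c(b3, b2, b1, b0)`.
#' @export
cubic_rubp <- function(gscb, j, params = leaf_params()) {
  p <- as_leaf_params(params)
  if (j < 0) stop("electron transport rate must be >= 0", call. = FALSE)
  k1 <- p$ca - p$gamma_star
  k2 <- p$ca + 2 * p$gamma_star
  g0m <- p$g0 + p$gm
  c(4 * gscb,
    4 * g0m - j * gscb - 4 * k2 * p$gm * gscb,
    k1 * p$gm * j * gscb - 4 * k2 * p$gm * p$g0 - j * g0m,
    k1 * p$gm * j * p$g0)
}

# All real roots of a cubic given coefficients c(c3, c2, c1, c0); degenerate
# leading coefficients reduce the degree. Roots are Newton-polished on the
# polynomial so the downstream implicit-equation residual is at machine
# precision.
solve_cubic_real <- function(coeffs, imag_tol = 1e-8) {
  c3 <- coeffs[1]; c2 <- coeffs[2]; c1 <- coeffs[3]; c0 <- coeffs[4]
  if (c3 == 0) {
    if (c2 == 0) {
      if (c1 == 0) return(numeric(0))
      return(-c0 / c1)
    }
    disc <- c1^2 - 4 * c2 * c0
    if (disc < 0) return(numeric(0))
    sq <- sqrt(disc)
    return(sort(c((-c1 - sq) / (2 * c2), (-c1 + sq) / (2 * c2))))
  }
  z <- polyroot(c(c0, c1, c2, c3))
  re <- Re(z)[abs(Im(z)) <= imag_tol * pmax(1, abs(Re(z)))]
  if (!length(re)) return(re)
  for (i in 1:3) {  # Newton polish
    f <- ((c3 * re + c2) * re + c1) * re + c0
    df <- (3 * c3 * re + 2 * c2) * re + c1
    re <- re - ifelse(df != 0, f / df, 0)
  }
  sort(re)
}

#' Select the admissible root of a steady-state cubic
#'
#' Among the real roots, returns the smallest one that is physically
#' admissible: `A >= 0`, implied chloroplastic CO2 in `(0, Ca]`, and implied
#' target conductance `G = g0 + gscb * A >= g0`. Degenerate quadratic and
#' linear cases (vanishing leading coefficients) are handled by the same
#' root finder.
#'
#' @param coeffs numeric vector `c(c3, c2, c1, c0)` from [cubic_rubisco()]
#'   or [cubic_rubp()].
#' @inheritParams cubic_rubisco
#' @return The admissible assimilation rate A, umol CO2 m-2 s-1.
#' @export
solve_admissible_root <- function(coeffs, gscb, params = leaf_params()) {
  p <- as_leaf_params(params)
  roots <- solve_cubic_real(coeffs)
  tol <- 1e-9
  for (a in roots) {
    if (a < -tol) next
    a_adm <- max(a, 0)
    g <- p$g0 + gscb * a_adm
    if (g < p$g0 - tol || g <= 0) next
    cc <- cc_from_a(a_adm, g, p)
    if (cc <= 0 || cc > p$ca + tol) next
    return(a_adm)
  }
  stop("no admissible root among {",
       paste(signif(roots, 6), collapse = ", "),
       "} for gscb = ", signif(gscb, 6), call. = FALSE)
}

#' Steady-state photosynthesis and target conductance
#'
#' Solves the coupled steady state of the biochemical demand functions, the
#' CO2 diffusion drawdown and the stomatal target model: both branch cubics
#' are solved with the same target slope, the net rate is the minimum of the
#' Rubisco- and RuBP-limited branches, and the target conductance and
#' chloroplastic CO2 follow from that rate.
#'
#' @param de vapour pressure deficit, kPa.
#' @param psi_m mesophyll water potential, MPa.
#' @param iinc incident PPFD, umol photon m-2 s-1.
#' @inheritParams electron_transport
#' @return A list: `a` (net rate, umol m-2 s-1), `ac`, `aj` (branch rates),
#'   `g` (target conductance to CO2, mol m-2 s-1), `cc` (umol mol-1),
#'   `j`, `gscb`, and `limitation` (`"rubisco"` or `"rubp"`).
#' @examples
#' steady_state_photosynthesis(de = 1, psi_m = -0.1, iinc = 500)
#' @export
steady_state_photosynthesis <- function(de, psi_m, iinc,
                                        params = leaf_params()) {
  p <- as_leaf_params(params)
  gscb <- target_coefficient(de, psi_m, p)
  j <- electron_transport(iinc, p)
  ac <- solve_admissible_root(cubic_rubisco(gscb, p), gscb, p)
  aj <- if (j <= 0) 0 else
    solve_admissible_root(cubic_rubp(gscb, j, p), gscb, p)
  a <- min(ac, aj)
  g <- p$g0 + gscb * a
  list(a = a, ac = ac, aj = aj, g = g, cc = cc_from_a(a, g, p),
       j = j, gscb = gscb,
       limitation = if (ac <= aj) "rubisco" else "rubp")
}

#' Instantaneous assimilation at the current stomatal conductance
#'
#' With the stomatal conductance fixed at its current (generally
#' non-steady-state) value, the diffusion drawdown is linear in A
#' (`Cc = Ca - rt * A` with `rt = 1/gsc + 1/gm`) and each demand branch
#' reduces to a quadratic; the smaller root of each is physical and the net
#' rate is the branch minimum.
#'
#' @param gsc current stomatal conductance to CO2, mol m-2 s-1 (> 0).
#' @inheritParams steady_state_photosynthesis
#' @return A list: `a` (net rate; `rd` is subtracted when the `subtract_rd`
#'   parameter is set), `ac`, `aj`, `cc`, `limitation`.
#' @export
instantaneous_assimilation <- function(gsc, iinc, params = leaf_params()) {
  p <- as_leaf_params(params)
  if (any(gsc <= 0)) stop("gsc must be positive", call. = FALSE)
  rt <- 1 / gsc + 1 / p$gm
  k1 <- p$ca - p$gamma_star
  ac <- quad_smaller_root(rt, -(p$ca + p$km + p$vcmax * rt), p$vcmax * k1)
  j <- electron_transport(iinc, p)
  aj <- if (j <= 0) 0 else {
    k2 <- p$ca + 2 * p$gamma_star
    quad_smaller_root(4 * rt, -(4 * k2 + j * rt), j * k1)
  }
  a <- min(ac, aj)
  cc <- p$ca - rt * a
  a_out <- if (p$subtract_rd) a - p$rd else a
  list(a = a_out, ac = ac, aj = aj, cc = cc,
       limitation = if (ac <= aj) "rubisco" else "rubp")
}

# Smaller root of a*x^2 + b*x + c = 0 with a > 0, computed in the
# cancellation-free form 2c / (-b + sqrt(b^2 - 4ac)).
quad_smaller_root <- function(a, b, c) {
  disc <- b^2 - 4 * a * c
  if (disc < 0)
    stop("no real root of the assimilation quadratic", call. = FALSE)
  2 * c / (-b + sqrt(disc))
}
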