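#' Vapour pressure deficit of the ambient air
#'
#' `(1 - hr/100) * a1 * exp(a2 * Tc / (a3 + Tc))` with `Tc = Ta - 273.16`,
#' i.e. the Magnus saturation pressure scaled by the saturation deficit.
#'
#' @param ta air temperature, K (vectorised).
#' @param hr relative humidity, percent, in \[0, 100\] (0 gives the
#'   saturation pressure itself).
#' @param params a [leaf_params()] object.
#' @return Vapour pressure deficit in kPa (>= 0).
#' @export
vpd <- function(ta, hr, params = leaf_params()) {
  p <- as_leaf_params(params)
  if (any(hr < 0 | hr > 100))
    stop("relative humidity must lie in [0, 100]", call. = FALSE)
  tc <- ta - 273.16
  if (any(p$a3 + tc <= 0))
    stop("temperature outside the domain of the saturation curve",
         call. = FALSE)
  (1 - hr / 100) * p$a1 * exp(p$a2 * tc / (p$a3 + tc))
}

#' Slope of the vapour-pressure curve
#'
#' Literal model form `a2 * a3 * de / (a3 + Ta - 273.16)^2`, proportional to
#' the ambient deficit `de`. With `slope_mode = "saturation"` the saturation
#' vapour pressure replaces `de`, which is the textbook Penman-Monteith
#' slope; the literal form is the default.
#'
#' @inheritParams vpd
#' @param de vapour pressure deficit, kPa.
#' @param mode `"literal"` or `"saturation"`; defaults to the `slope_mode`
#'   parameter.
#' @return Slope in kPa K-1.
#' @export
svp_slope <- function(ta, de, params = leaf_params(), mode = NULL) {
  p <- as_leaf_params(params)
  if (is.null(mode)) mode <- p$slope_mode
  mode <- match.arg(mode, c("literal", "saturation"))
  tc <- ta - 273.16
  e <- if (mode == "literal") de else p$a1 * exp(p$a2 * tc / (p$a3 + tc))
  p$a2 * p$a3 * e / (p$a3 + tc)^2
}

#' Total conductance to water vapour
#'
#' Stomatal and boundary-layer conductances in series:
#' `gbw * gsw / (gsw + gbw)`.
#'
#' @param gsw stomatal conductance to water vapour, mol m-2 s-1 (>= 0).
#' @inheritParams vpd
#' @return Total conductance in mol H2O m-2 s-1, bounded by `min(gsw, gbw)`.
#' @export
total_conductance <- function(gsw, params = leaf_params()) {
  p <- as_leaf_params(params)
  if (any(gsw < 0)) stop("gsw must be non-negative", call. = FALSE)
  den <- gsw + p$gbw
  ifelse(den == 0, 0, p$gbw * gsw / den)
}

#' Net radiation absorbed by the leaf
#'
#' Linear conversion from PPFD, `Rn = k_rad * ppfd`. The default
#' `k_rad = 0.4376` J umol-1 maps PPFD to PAR energy (4.57 umol J-1) doubled
#' to approximate total shortwave load.
#'
#' @param ppfd incident PPFD, umol photon m-2 s-1.
#' @inheritParams vpd
#' @return Net radiation in J m-2 s-1.
#' @export
net_radiation <- function(ppfd, params = leaf_params()) {
  p <- as_leaf_params(params)
  if (any(ppfd < 0)) stop("ppfd must be non-negative", call. = FALSE)
  p$k_rad * ppfd
}

#' Leaf temperature from the linearised energy balance
#'
#' Closed-form solution of the leaf energy balance
#' `Rn - Gi = H + lambda * E` with the vapour pressure difference linearised
#' about air temperature:
#' `Tl = Ta + (raH*rtw*gamma*(Rn - Gi) - raH*rho_a*cp*de) /
#' (rho_a*cp*(gamma*rtw + s*raH))`, where `rtw = 1/gtw` and
#' `raH = 1.15/gbw` is the resistance to diffusive heat transfer.
#'
#' @inheritParams svp_slope
#' @param s slope of the vapour-pressure curve, kPa K-1.
#' @param gtw total conductance to water vapour, mol m-2 s-1 (> 0).
#' @param rn net radiation, J m-2 s-1.
#' @return Leaf temperature in K.
#' @export
leaf_temperature <- function(ta, de, s, gtw, rn, params = leaf_params()) {
  p <- as_leaf_params(params)
  if (any(gtw <= 0)) stop("gtw must be positive", call. = FALSE)
  rtw <- 1 / gtw
  ra_h <- 1.15 / p$gbw
  rhocp <- p$rho_a * p$cp
  den <- rhocp * (p$gamma * rtw + s * ra_h)
  if (any(den == 0)) stop("degenerate energy-balance denominator",
                          call. = FALSE)
  ta + (ra_h * rtw * p$gamma * (rn - p$g_i) - ra_h * rhocp * de) / den
}

#' Transpiration rate (Penman-Monteith form)
#'
#' `E = gtw * rho_a * cp * (de + s * (Tl - Ta)) / (lambda * gamma)`: the
#' leaf-to-air vapour pressure difference, linearised with the slope `s`,
#' driven through the total conductance.
#'
#' @inheritParams leaf_temperature
#' @param tl leaf temperature, K.
#' @return Transpiration in mol H2O m-2 s-1.
#' @export
transpiration <- function(tl, ta, de, s, gtw, params = leaf_params()) {
  p <- as_leaf_params(params)
  if (any(gtw < 0)) stop("gtw must be non-negative", call. = FALSE)
  gtw * p$rho_a * p$cp * (de + s * (tl - ta)) / (p$lam * p$gamma)
}
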