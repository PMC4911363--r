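# Ratio of the diffusivities of CO2 and water vapour in air: g_sw = 1.6 g_sc.
H2O_CO2_DIFF_RATIO <- 1.6

# Floor offset keeping logarithm arguments of the kinetic law positive.
GSW_EPS <- 1e-6

#' Water-potential down-regulation of the stomatal target
#'
#' Sigmoidal gating factor
#' `(1 + exp(sf * psi_r)) / (1 + exp(sf * (psi_r - psi_m)))`: equals 1 at
#' zero water potential, tends to 0 as the mesophyll dries, and is strictly
#' increasing in `psi_m`.
#'
#' @param psi_m mesophyll water potential, MPa (vectorised).
#' @param params a [leaf_params()] object.
#' @return Dimensionless factor in (0, 1 + exp(sf * psi_r)).
#' @export
f_psi <- function(psi_m, params = leaf_params()) {
  p <- as_leaf_params(params)
  expo <- pmin(p$sf * (p$psi_r - psi_m), 700)  # overflow guard
  (1 + exp(p$sf * p$psi_r)) / (1 + exp(expo))
}

#' Slope of the steady-state stomatal target
#'
#' The steady-state target conductance is `G = g0 + gscb * A` with
#' `gscb = (1 + g1 / sqrt(de)) * f_psi(psi_m) / Ca` (the unified
#' optimal-stomatal form, gated by leaf water status). The deficit is
#' floored at `de_min` to avoid the square-root singularity at saturation;
#' the intercept `g0` is not gated.
#'
#' @param de vapour pressure deficit, kPa.
#' @param psi_m mesophyll water potential, MPa.
#' @param ca ambient CO2 mole fraction, umol mol-1; defaults to the `ca`
#'   parameter.
#' @inheritParams f_psi
#' @return Slope `gscb` in mol CO2 m-2 s-1 per umol CO2 m-2 s-1.
#' @export
target_coefficient <- function(de, psi_m, params = leaf_params(),
                               ca = NULL) {
  p <- as_leaf_params(params)
  if (is.null(ca)) ca <- p$ca
  if (any(ca <= 0)) stop("ca must be positive", call. = FALSE)
  de <- pmax(de, p$de_min)
  (1 + p$g1 / sqrt(de)) * f_psi(psi_m, p) / ca
}

#' Rate of change of stomatal conductance
#'
#' Target-tracking kinetic law
#' `dgsw/dt = alpha_g * ln((1.6 G - r0) / (gsw - r0)) * (gsw - r0)`.
#' Both `gsw` and `1.6 G` are floored at `r0 + 1e-6` before taking the
#' logarithm, which realises the initial-lag behaviour that `r0` encodes.
#'
#' @param gsw current stomatal conductance to water vapour, mol m-2 s-1.
#' @param g_target steady-state target conductance to CO2, mol m-2 s-1.
#' @inheritParams f_psi
#' @return Derivative in mol H2O m-2 s-1 per s. Positive while the stoma
#'   opens towards `1.6 * g_target`, zero at the target.
#' @export
gsw_derivative <- function(gsw, g_target, params = leaf_params()) {
  p <- as_leaf_params(params)
  floor_g <- p$r0 + GSW_EPS
  gt <- pmax(H2O_CO2_DIFF_RATIO * g_target, floor_g)
  gs <- pmax(gsw, floor_g)
  p$alpha_g * log((gt - p$r0) / (gs - p$r0)) * (gs - p$r0)
}

#' Simulate a stomatal induction curve at constant target
#'
#' Integrates the kinetic law forward in time under a fixed steady-state
#' target, starting from a near-closed stoma, and emits samples every
#' `sample_every` seconds (5 s matches gas-exchange logger protocols). Under
#' a constant target the log-deviation from the target decays exponentially,
#' so each step uses the exact propagator and the trajectory is independent
#' of `dt`.
#'
#' @inheritParams f_psi
#' @param g_target constant target conductance to CO2, mol m-2 s-1; the
#'   stoma opens towards `1.6 * g_target`.
#' @param duration length of the experiment, s.
#' @param dt internal step, s (must divide `sample_every` sensibly).
#' @param gsw0 initial stomatal conductance, mol m-2 s-1; floored at
#'   `r0 + 1e-6`.
#' @param sample_every sampling interval of the output, s.
#' @return A data.frame with columns `t` (s) and `gsw` (mol m-2 s-1).
#' @examples
#' curve <- simulate_induction(leaf_params(), g_target = 0.15)
#' tail(curve, 1)  # near 1.6 * 0.15 = 0.24
#' @export
simulate_induction <- function(params = leaf_params(), g_target,
                               duration = 3600, dt = 1, gsw0 = 1e-3,
                               sample_every = 5) {
  p <- as_leaf_params(params)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  g_inf <- max(H2O_CO2_DIFF_RATIO * g_target, p$r0 + GSW_EPS)
  g <- max(gsw0, p$r0 + GSW_EPS)
  t <- seq(0, duration, by = sample_every)
  u0 <- log((g - p$r0) / (g_inf - p$r0))
  gsw <- p$r0 + (g_inf - p$r0) * exp(u0 * exp(-p$alpha_g * t))
  data.frame(t = t, gsw = gsw)
}

#' Fit stomatal kinetic parameters to an induction curve
#'
#' Estimates the time constant `alpha_g` and initial-lag conductance `r0` by
#' nonlinear least squares of the constant-target solution of the kinetic
#' law against an observed opening time course. The plateau conductance and
#' the initial conductance are fitted jointly with the kinetic parameters
#' under box constraints (`r0` cannot exceed the smallest observation).
#'
#' @param data a data.frame whose first two columns are time (s) and
#'   stomatal conductance (mol m-2 s-1), e.g. the output of
#'   [simulate_induction()]; at least 20 points spanning the rise.
#' @param start optional named list overriding the self-derived starting
#'   values (`alpha_g`, `r0`, `g_inf`, `g_start`).
#' @return An object of class `induction_fit` with methods [coef()],
#'   [print()], [summary()], [predict()], [fitted()], [residuals()] and
#'   [plot()]. `coef()` returns the `alpha_g` and `r0` estimates.
#' @examples
#' curve <- simulate_induction(leaf_params(), g_target = 0.15)
#' fit <- fit_induction(curve)
#' coef(fit)
#' @export
fit_induction <- function(data, start = NULL) {
  d <- as.data.frame(data)
  if (ncol(d) < 2) stop("'data' needs time and gsw columns", call. = FALSE)
  t <- as.numeric(d[[1]]); g <- as.numeric(d[[2]])
  keep <- is.finite(t) & is.finite(g)
  t <- t[keep]; g <- g[keep]
  if (length(t) < 20)
    stop("need at least 20 points spanning the stomatal rise",
         call. = FALSE)
  if (diff(range(g)) < 1e-8 * max(1, max(abs(g))))
    stop("conductance series is constant; kinetic parameters are not ",
         "identifiable", call. = FALSE)
  t <- t - t[1]
  gmin <- min(g); gmax <- max(g)
  # crude time-scale guess: time to cover 63% of the observed rise
  i63 <- which(g >= gmin + 0.63 * (gmax - gmin))[1]
  ag0 <- 1 / max(t[i63], diff(range(t)) / 20)
  s0 <- list(alpha_g = ag0, r0 = 0.5 * gmin,
             g_inf = mean(g[t >= stats::quantile(t, 0.9)]),
             g_start = max(gmin, 1e-6))
  if (!is.null(start)) s0[names(start)] <- start
  model <- function(alpha_g, r0, g_inf, g_start, t) {
    num <- pmax(g_start - r0, 1e-12)
    den <- pmax(g_inf - r0, 1e-10)
    r0 + den * exp(log(num / den) * exp(-alpha_g * t))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ model(alpha_g, r0, g_inf, g_start, t),
      start = s0,
      lower = c(alpha_g = 1e-7, r0 = 0, g_inf = gmin, g_start = 1e-9),
      upper = c(alpha_g = 10, r0 = gmin, g_inf = 10 * gmax,
                g_start = gmax),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("induction fit failed to converge: ", conditionMessage(e),
           call. = FALSE))
  est <- stats::coef(fit)
  res <- stats::residuals(fit)
  structure(
    list(coefficients = est[c("alpha_g", "r0")],
         full_coefficients = est,
         fit = fit,
         data = data.frame(t = t, gsw = g),
         residual_norm = sqrt(sum(res^2)),
         converged = fit$convInfo$isConv %||% TRUE),
    class = "induction_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.induction_fit <- function(object, full = FALSE, ...) {
  if (full) object$full_coefficients else object$coefficients
}

#' @export
print.induction_fit <- function(x, ...) {
  cat("Stomatal induction curve fit\n")
  cat(sprintf("  alpha_g = %.6g s-1,  r0 = %.6g mol m-2 s-1\n",
              x$coefficients[["alpha_g"]], x$coefficients[["r0"]]))
  cat(sprintf("  plateau = %.4g, start = %.4g mol m-2 s-1\n",
              x$full_coefficients[["g_inf"]],
              x$full_coefficients[["g_start"]]))
  cat(sprintf("  %d points, residual norm %.3g, converged: %s\n",
              nrow(x$data), x$residual_norm, x$converged))
  invisible(x)
}

#' @export
summary.induction_fit <- function(object, ...) {
  s <- summary(object$fit)
  cat("Stomatal induction curve fit (nonlinear least squares)\n\n")
  stats::printCoefmat(s$coefficients)
  cat(sprintf("\nResidual standard error: %.4g on %d degrees of freedom\n",
              s$sigma, s$df[2]))
  invisible(s)
}

#' @export
predict.induction_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t else
    as.numeric(if (is.data.frame(newdata)) newdata[[1]] else newdata)
  e <- object$full_coefficients
  num <- max(e[["g_start"]] - e[["r0"]], 1e-12)
  den <- max(e[["g_inf"]] - e[["r0"]], 1e-10)
  e[["r0"]] + den * exp(log(num / den) * exp(-e[["alpha_g"]] * t))
}

#' @export
fitted.induction_fit <- function(object, ...) predict(object)

#' @export
residuals.induction_fit <- function(object, ...) {
  object$data$gsw - fitted(object)
}

#' @export
plot.induction_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$gsw, pch = 16, cex = 0.5,
                 xlab = "time (s)",
                 ylab = expression(g[sw] ~ (mol ~ m^-2 ~ s^-1)), ...)
  graphics::lines(x$data$t, fitted(x), col = "red3", lwd = 2)
  invisible(x)
}
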