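#' Preset value grids for the sensitivity scans
#'
#' Returns the scan grids used in the sensitivity analysis of daily water
#' use efficiency: the explicit stomatal-speed and initial-lag value sets, a
#' denser 15-point log-spaced speed grid spanning the same extremes, the
#' percent-change grids for the target slope `g1` (-40 to +90 %) and the
#' mesophyll conductance `gm` (-40 to +500 %), and the fluctuation-period
#' grid (150 s to 2 h).
#'
#' @return A named list of numeric vectors.
#' @export
scan_presets <- function() {
  list(
    alpha_g = sort(c(4.0516e-3, 0.00682, 0.00338, 0.00134, 0.00109)),
    alpha_g_grid15 = exp(seq(log(0.00109), log(0.0101), length.out = 15)),
    r0 = sort(c(2.674e-3, 0.0106, 0.0012, 0.0002)),
    g1_percent = seq(-40, 90, by = 10),
    gm_percent = c(-40, -20, 0, 33, 67, 100, 167, 300, 400, 500),
    period = c(150, 300, 600, 900, 1800, 2700, 3600, 5400, 7200)
  )
}

#' Sensitivity scan of daily WUE over one model parameter
#'
#' Runs one full diurnal simulation per parameter value, everything else
#' held fixed, and tabulates the daily assimilation and transpiration
#' integrals and their ratio. Values may be given directly or as percent
#' changes relative to the current default of the parameter.
#'
#' @param param name of the scanned parameter (e.g. `"alpha_g"`, `"r0"`,
#'   `"g1"`, `"gm"`).
#' @param values numeric vector of absolute parameter values; exactly one of
#'   `values` / `percent` must be given.
#' @param percent numeric vector of percent changes relative to
#'   `params[[param]]` (e.g. `c(-40, 0, 90)`).
#' @param forcing forcing passed on to [simulate_leaf()] (an ideal-day
#'   scenario or a climate data.frame).
#' @param params base parameter set.
#' @param dt,t_start,t_end,window simulation and integration controls, see
#'   [simulate_leaf()] and [daily_wue()].
#' @return A data.frame of class `wue_scan` with columns `param`, `value`,
#'   `wue`, `int_a`, `int_e`, `scenario`, `status`. A failed run annotates
#'   its row (`status`) instead of aborting the scan.
#' @examples
#' day <- ideal_day_params("sunny", period = 3600)
#' scan_parameter("g1", percent = c(-40, 0, 90), forcing = day, dt = 30)
#' @export
scan_parameter <- function(param, values = NULL, percent = NULL,
                           forcing, params = leaf_params(), dt = 1,
                           t_start = 6 * 3600, t_end = 21 * 3600,
                           window = c(6, 20) * 3600) {
  p <- as_leaf_params(params)
  if (!param %in% names(p))
    stop("unknown parameter '", param, "'", call. = FALSE)
  if (is.null(values) == is.null(percent))
    stop("give exactly one of 'values' or 'percent'", call. = FALSE)
  if (!is.null(percent)) values <- p[[param]] * (1 + percent / 100)
  if (any(!is.finite(values)))
    stop("scan values must be finite", call. = FALSE)
  scen <- describe_scenario(forcing)
  rows <- lapply(values, function(v) {
    st <- tryCatch({
      pv <- p
      pv[[param]] <- v
      sim <- simulate_leaf(forcing, pv, dt = dt, t_start = t_start,
                           t_end = t_end)
      w <- daily_wue(sim, window)
      data.frame(param = param, value = v, wue = w$wue, int_a = w$int_a,
                 int_e = w$int_e, scenario = scen, status = "ok")
    }, error = function(e)
      data.frame(param = param, value = v, wue = NA_real_,
                 int_a = NA_real_, int_e = NA_real_, scenario = scen,
                 status = paste0("error: ", conditionMessage(e))))
    st
  })
  structure(do.call(rbind, rows), class = c("wue_scan", "data.frame"))
}

#' Sensitivity of daily WUE to the light fluctuation period
#'
#' Regenerates the ideal-day forcing for each period (same daytime mean and
#' amplitude, same day length) and simulates each day.
#'
#' @param periods numeric vector of fluctuation half-periods, s (> 0).
#' @param kind `"sunny"` or `"cloudy"` ideal-day scenario.
#' @param params,dt,t_start,t_end,window see [scan_parameter()].
#' @param ... further arguments passed to [ideal_day_params()] (e.g. `Ia =
#'   0` for a constant-light control).
#' @return A `wue_scan` data.frame with one row per period.
#' @export
scan_period <- function(periods, kind = c("sunny", "cloudy"),
                        params = leaf_params(), dt = 1,
                        t_start = 6 * 3600, t_end = 21 * 3600,
                        window = c(6, 20) * 3600, ...) {
  kind <- match.arg(kind)
  if (any(periods <= 0)) stop("periods must be positive", call. = FALSE)
  p <- as_leaf_params(params)
  rows <- lapply(periods, function(pd) {
    tryCatch({
      day <- ideal_day_params(kind, period = pd, ...)
      sim <- simulate_leaf(day, p, dt = dt, t_start = t_start,
                           t_end = t_end)
      w <- daily_wue(sim, window)
      data.frame(param = "period", value = pd, wue = w$wue,
                 int_a = w$int_a, int_e = w$int_e,
                 scenario = paste0("ideal-", kind), status = "ok")
    }, error = function(e)
      data.frame(param = "period", value = pd, wue = NA_real_,
                 int_a = NA_real_, int_e = NA_real_,
                 scenario = paste0("ideal-", kind),
                 status = paste0("error: ", conditionMessage(e))))
  })
  structure(do.call(rbind, rows), class = c("wue_scan", "data.frame"))
}

#' @export
print.wue_scan <- function(x, ...) {
  cat(sprintf("WUE sensitivity scan of '%s' (%s), %d values\n",
              x$param[1], x$scenario[1], nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
plot.wue_scan <- function(x, ...) {
  ok <- x$status == "ok"
  graphics::plot(x$value[ok], x$wue[ok], type = "b", pch = 16,
                 xlab = x$param[1],
                 ylab = "daily WUE (mmol CO2 / mol H2O)", ...)
  invisible(x)
}

describe_scenario <- function(forcing) {
  if (inherits(forcing, "ideal_day"))
    sprintf("ideal-%s (p = %g s)", forcing$kind, forcing$period)
  else "climate series"
}

#' Write the synthetic fixture bundle
#'
#' Generates, deterministically for a given seed, the small plain-text
#' inputs that exercise the whole pipeline without any external data: ideal
#' sunny and cloudy climate CSVs, a noise-free and a 2 %-multiplicative-noise
#' stomatal induction curve from known kinetic parameters, and a malformed
#' climate file (out-of-range humidity) as a negative fixture.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the noise realisation.
#' @param params parameter set whose `alpha_g` and `r0` generate the
#'   induction curves.
#' @return Invisibly, a named character vector of the written file paths.
#' @export
make_fixtures <- function(dir, seed = 42, params = leaf_params()) {
  p <- as_leaf_params(params)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    sunny = file.path(dir, "ideal_sunny.csv"),
    cloudy = file.path(dir, "ideal_cloudy.csv"),
    induction_clean = file.path(dir, "induction_clean.csv"),
    induction_noisy = file.path(dir, "induction_noisy.csv"),
    malformed = file.path(dir, "malformed_climate.csv"))
  for (kind in c("sunny", "cloudy")) {
    day <- ideal_day_params(kind, period = 3600)
    utils::write.csv(ideal_forcing(day, dt = 60), paths[[kind]],
                     row.names = FALSE)
  }
  curve <- simulate_induction(p, g_target = 0.15, duration = 1800)
  utils::write.csv(curve, paths[["induction_clean"]], row.names = FALSE)
  set.seed(seed)
  noisy <- curve
  noisy$gsw <- noisy$gsw * (1 + stats::rnorm(nrow(noisy), 0, 0.02))
  utils::write.csv(noisy, paths[["induction_noisy"]], row.names = FALSE)
  writeLines(c("time,ppfd,ta,hr", "06:00:00,0,291.15,120",
               "06:01:00,5,291.15,100"), paths[["malformed"]])
  invisible(paths)
}
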