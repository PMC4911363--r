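#' Define a sinusoidal "ideal day" climate scenario
#'
#' An ideal day replaces recorded greenhouse climate with reproducible
#' sinusoidal light and temperature courses whose daytime means are fixed.
#' Light follows `Im + Ia * cos(pi * (t - t0) / p - pi)` within a 15-h
#' photoperiod and is zero outside it; the phase origin `t0` defaults to the
#' start of the photoperiod so the day begins at the minimum `Im - Ia`.
#' Temperature follows the same shape with mean `Tm` and amplitude `Ta_amp`,
#' delayed by `lag` seconds behind the light.
#'
#' @param kind `"sunny"` or `"cloudy"`; presets the daytime mean/amplitude of
#'   light to 237/137.02 (sunny) or 139/133.435 (cloudy) umol photon m-2 s-1.
#' @param period half-cycle `p` of the fluctuation in seconds (the light goes
#'   from minimum to maximum in `p` seconds); must be positive.
#' @param Im,Ia daytime mean and amplitude of light, umol photon m-2 s-1;
#'   defaults come from `kind`.
#' @param day_start,day_end photoperiod bounds in seconds since midnight
#'   (default 06:00 to 21:00, a 15-h photoperiod).
#' @param t0 phase origin, s; default `day_start`.
#' @param Tm,Ta_amp mean daytime air temperature (K) and its amplitude (K).
#'   The default Tm = 295.15 K (22 degC) and Ta_amp = 4 K apply to both kinds.
#' @param lag delay of the temperature wave behind the light wave, s.
#' @return An object of class `ideal_day`.
#' @examples
#' day <- ideal_day_params("cloudy", period = 3600)
#' ideal_light(day$day_start, day)  # Im - Ia at the phase origin
#' @export
ideal_day_params <- function(kind = c("sunny", "cloudy"), period = 3600,
                             Im = NULL, Ia = NULL,
                             day_start = 6 * 3600, day_end = 21 * 3600,
                             t0 = day_start, Tm = 295.15, Ta_amp = 4,
                             lag = 1800) {
  kind <- match.arg(kind)
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      period <= 0)
    stop("'period' must be a single positive number of seconds",
         call. = FALSE)
  if (is.null(Im)) Im <- switch(kind, sunny = 237, cloudy = 139)
  if (is.null(Ia)) Ia <- switch(kind, sunny = 137.02, cloudy = 133.435)
  if (day_end <= day_start)
    stop("'day_end' must exceed 'day_start'", call. = FALSE)
  if (Ia > Im)
    warning("light amplitude exceeds the mean; light will be clamped at 0",
            call. = FALSE)
  structure(list(kind = kind, Im = Im, Ia = Ia, period = period,
                 day_start = day_start, day_end = day_end, t0 = t0,
                 Tm = Tm, Ta_amp = Ta_amp, lag = lag),
            class = "ideal_day")
}

#' @export
print.ideal_day <- function(x, ...) {
  cat(sprintf(
    "Ideal %s day: Im = %g, Ia = %g umol m-2 s-1, half-period = %g s\n",
    x$kind, x$Im, x$Ia, x$period))
  cat(sprintf("  photoperiod %s-%s, Tm = %g K, Ta_amp = %g K, lag = %g s\n",
              fmt_hms(x$day_start), fmt_hms(x$day_end), x$Tm, x$Ta_amp,
              x$lag))
  invisible(x)
}

fmt_hms <- function(s) {
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60,
          round(s %% 60))
}

#' Sinusoidal light of an ideal day
#'
#' @param t time in seconds since midnight (vectorised).
#' @param day an [ideal_day_params()] object.
#' @return PPFD in umol photon m-2 s-1; 0 outside the photoperiod and never
#'   negative.
#' @export
ideal_light <- function(t, day) {
  stopifnot(inherits(day, "ideal_day"))
  out <- day$Im + day$Ia * cos(pi * (t - day$t0) / day$period - pi)
  out <- pmax(out, 0)
  out[t < day$day_start | t > day$day_end] <- 0
  out
}

#' Sinusoidal air temperature of an ideal day
#'
#' Same waveform as [ideal_light()] with mean `Tm`, amplitude `Ta_amp`, and
#' the phase delayed by `day$lag` seconds. Outside the (lag-shifted)
#' photoperiod the wave is held at its boundary value, so night temperature
#' is defined and continuous.
#'
#' @inheritParams ideal_light
#' @return Air temperature in K.
#' @export
ideal_temperature <- function(t, day) {
  stopifnot(inherits(day, "ideal_day"))
  ts <- pmin(pmax(t - day$lag, day$day_start), day$day_end)
  day$Tm + day$Ta_amp * cos(pi * (ts - day$t0) / day$period - pi)
}

#' Relative humidity from air temperature
#'
#' Hyperbolic decay of greenhouse relative humidity with air temperature,
#' `hr = 1173.613 / ((Ta - 273.16) - 6.3458)`, clamped at 100 %. The relation
#' is only defined for air temperatures above 6.3458 degC.
#'
#' @param Ta air temperature, K (vectorised).
#' @return Relative humidity in percent, in (0, 100].
#' @examples
#' hr_from_ta(293.16)  # about 85.95 at 20 degC
#' @export
hr_from_ta <- function(Ta) {
  tc <- Ta - 273.16
  if (any(tc <= 6.3458))
    stop("hr_from_ta() is only valid for air temperatures above 6.3458 degC",
         call. = FALSE)
  pmin(1173.613 / (tc - 6.3458), 100)
}

#' Generate a climate forcing table for an ideal day
#'
#' Samples the ideal-day light and temperature waves on a regular grid and
#' derives relative humidity from temperature. The result has the same
#' columns as a climate CSV read by [read_climate()] and can be passed
#' directly to [simulate_leaf()].
#'
#' @param day an [ideal_day_params()] object.
#' @param dt sampling interval, s.
#' @param from,to time span covered (seconds since midnight); defaults to the
#'   photoperiod.
#' @param ca ambient CO2 mole fraction, umol mol-1.
#' @return A data.frame with columns `time`, `ppfd`, `ta` (K), `hr`, `ca`.
#' @export
ideal_forcing <- function(day, dt = 60, from = day$day_start,
                          to = day$day_end, ca = 380) {
  stopifnot(inherits(day, "ideal_day"))
  t <- seq(from, to, by = dt)
  ta <- ideal_temperature(t, day)
  data.frame(time = t, ppfd = ideal_light(t, day), ta = ta,
             hr = hr_from_ta(ta), ca = ca)
}

#' Read a climate CSV file
#'
#' Expects a header with columns `time`, `ppfd`, `ta`, `hr` and optionally
#' `ca` (defaulted to 380 umol mol-1 when absent). `time` may be given as
#' seconds since midnight or as `HH:MM:SS`. Temperature is auto-detected as
#' Celsius when all values are below 150 and converted to Kelvin with a
#' message. Rows must be strictly increasing in time and satisfy the
#' physical invariants (ppfd >= 0, 0 < hr <= 100, ca > 0).
#'
#' @param path path to a CSV file.
#' @return A data.frame with columns `time` (s), `ppfd`, `ta` (K), `hr`, `ca`.
#' @export
read_climate <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time", "ppfd", "ta", "hr")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols))
    stop("climate file '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tm <- d$time
  if (is.character(tm)) {
    parts <- strsplit(tm, ":", fixed = TRUE)
    bad <- which(!vapply(parts, length, 0L) %in% c(1L, 3L))
    if (length(bad))
      stop("unparseable time in row ", bad[1], ": '", tm[bad[1]], "'",
           call. = FALSE)
    tm <- vapply(parts, function(x) {
      x <- suppressWarnings(as.numeric(x))
      if (anyNA(x)) return(NA_real_)
      if (length(x) == 3L) x[1] * 3600 + x[2] * 60 + x[3] else x[1]
    }, 0)
  }
  tm <- as.numeric(tm)
  if (anyNA(tm))
    stop("unparseable time in row ", which(is.na(tm))[1], call. = FALSE)
  for (col in c("ppfd", "ta", "hr")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(v))
      stop("unparseable '", col, "' in row ", which(is.na(v))[1],
           call. = FALSE)
    d[[col]] <- v
  }
  if (is.unsorted(tm, strictly = TRUE)) {
    if (anyDuplicated(tm))
      stop("duplicate timestamp in row ", anyDuplicated(tm), call. = FALSE)
    stop("timestamps are not increasing at row ",
         which(diff(tm) <= 0)[1] + 1L, call. = FALSE)
  }
  if (all(d$ta < 150)) {
    message("temperature column appears to be in degC; converting to K")
    d$ta <- d$ta + 273.15
  }
  if (any(d$ppfd < 0))
    stop("negative ppfd in row ", which(d$ppfd < 0)[1], call. = FALSE)
  if (any(d$hr <= 0 | d$hr > 100))
    stop("relative humidity out of (0, 100] in row ",
         which(d$hr <= 0 | d$hr > 100)[1], call. = FALSE)
  if (is.null(d$ca)) d$ca <- 380
  if (any(d$ca <= 0))
    stop("non-positive ca in row ", which(d$ca <= 0)[1], call. = FALSE)
  data.frame(time = tm, ppfd = d$ppfd, ta = d$ta, hr = d$hr, ca = d$ca)
}

#' Interpolate a climate series at arbitrary times
#'
#' Linear interpolation of every forcing variable between the bracketing
#' samples. Exact at sample points.
#'
#' @param series a climate data.frame as returned by [read_climate()] or
#'   [ideal_forcing()].
#' @param t times in seconds since midnight (vectorised); must lie within the
#'   span of `series`.
#' @return A data.frame with one row per requested time.
#' @export
env_at <- function(series, t) {
  if (any(t < series$time[1] | t > series$time[nrow(series)]))
    stop("requested time outside the span of the climate series",
         call. = FALSE)
  interp <- function(col) stats::approx(series$time, series[[col]],
                                        xout = t)$y
  data.frame(time = t, ppfd = interp("ppfd"), ta = interp("ta"),
             hr = interp("hr"), ca = interp("ca"))
}
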