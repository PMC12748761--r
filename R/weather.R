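#' Synthetic tropical daily weather
#'
#' Multi-year daily weather series with the statistical structure of
#' tropical African cassava-zone climates: a seasonal temperature sinusoid
#' with a fixed diurnal range, two-state (wet/dry) Markov rain occurrence
#' restricted to configured wet-season windows, right-skewed gamma wet-day
#' rain amounts calibrated to a target annual total, and solar/humidity
#' baselines shifted on wet days (solar down, humidity up).  Years are 365
#' days; no leap handling.
#'
#' @name synthetic_weather
NULL

#' Define a climate regime
#'
#' @param name regime identifier.
#' @param mean_temp mean annual temperature, degrees C.
#' @param seasonal_amp amplitude of the seasonal temperature sinusoid, C.
#' @param diurnal_range mean daily tmax - tmin, degrees C.
#' @param temp_sd day-to-day temperature noise s.d., degrees C.
#' @param peak_doy day of year of the seasonal temperature maximum.
#' @param wet_windows list of `c(start, end)` day-of-year intervals of the
#'   wet season(s).
#' @param p_dw,p_ww wet-season dry-to-wet and wet-to-wet daily transition
#'   probabilities.
#' @param p_dw_off off-season dry-to-wet probability (residual showers).
#' @param rain_shape gamma shape of wet-day rain amounts (> 0).
#' @param annual_rain target mean annual rainfall, mm (>= 0); the gamma
#'   scale is derived from it and the stationary wet-day frequency.
#' @param solar_base clear-day solar radiation, MJ m-2 d-1.
#' @param solar_wet_adj additive solar shift on wet days (negative).
#' @param rh_base dry-day relative humidity, percent.
#' @param rh_wet_adj additive humidity shift on wet days (positive).
#' @return a `climate_regime` object.
#' @export
climate_regime <- function(name, mean_temp, seasonal_amp, diurnal_range,
                           temp_sd = 1, peak_doy = 90,
                           wet_windows = list(c(75, 180), c(250, 310)),
                           p_dw = 0.4, p_ww = 0.7, p_dw_off = 0.02,
                           rain_shape = 0.8, annual_rain = 1200,
                           solar_base = 21, solar_wet_adj = -6,
                           rh_base = 60, rh_wet_adj = 20) {
  for (fld in c("p_dw", "p_ww", "p_dw_off")) {
    v <- get(fld)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("climate_regime: probability '", fld, "' must be in [0, 1]")
  }
  if (rain_shape <= 0) stop("climate_regime: rain_shape must be > 0")
  if (annual_rain < 0) stop("climate_regime: annual_rain must be >= 0")
  if (diurnal_range < 0) stop("climate_regime: diurnal_range must be >= 0")
  structure(list(name = name, mean_temp = mean_temp,
                 seasonal_amp = seasonal_amp, diurnal_range = diurnal_range,
                 temp_sd = temp_sd, peak_doy = peak_doy,
                 wet_windows = wet_windows, p_dw = p_dw, p_ww = p_ww,
                 p_dw_off = p_dw_off, rain_shape = rain_shape,
                 annual_rain = annual_rain, solar_base = solar_base,
                 solar_wet_adj = solar_wet_adj, rh_base = rh_base,
                 rh_wet_adj = rh_wet_adj),
            class = "climate_regime")
}

#' Preset climate regimes
#'
#' Four regimes spanning the rainfall gradient of the African cassava
#' zone, from the humid forest belt to the arid margin below the ~750-800
#' mm isohyets that bound cassava production.
#'
#' @return named list of [climate_regime()] objects:
#'   `humid` (1200 mm, bimodal rains), `subhumid` (900 mm),
#'   `semiarid` (550 mm, single short season), `arid` (300 mm).
#' @export
climate_presets <- function() {
  list(
    humid = climate_regime("humid", mean_temp = 26, seasonal_amp = 2,
                           diurnal_range = 8, annual_rain = 1200,
                           wet_windows = list(c(75, 185), c(250, 315)),
                           p_dw = 0.45, p_ww = 0.75, p_dw_off = 0.04,
                           rh_base = 65, rh_wet_adj = 22),
    subhumid = climate_regime("subhumid", mean_temp = 27, seasonal_amp = 3,
                              diurnal_range = 10, annual_rain = 900,
                              wet_windows = list(c(90, 180), c(255, 305)),
                              p_dw = 0.38, p_ww = 0.70, p_dw_off = 0.02,
                              rh_base = 55, rh_wet_adj = 25),
    semiarid = climate_regime("semiarid", mean_temp = 28, seasonal_amp = 4,
                              diurnal_range = 13, annual_rain = 550,
                              wet_windows = list(c(150, 250)),
                              p_dw = 0.30, p_ww = 0.62, p_dw_off = 0.01,
                              rh_base = 45, rh_wet_adj = 28, solar_base = 23),
    arid = climate_regime("arid", mean_temp = 29, seasonal_amp = 5,
                          diurnal_range = 15, annual_rain = 300,
                          wet_windows = list(c(170, 240)),
                          p_dw = 0.22, p_ww = 0.55, p_dw_off = 0.005,
                          rh_base = 35, rh_wet_adj = 30, solar_base = 24)
  )
}

resolve_regime <- function(regime) {
  if (inherits(regime, "climate_regime")) return(regime)
  if (is.character(regime) && length(regime) == 1L) {
    presets <- climate_presets()
    if (!regime %in% names(presets))
      stop("unknown climate regime '", regime, "'; presets: ",
           paste(names(presets), collapse = ", "))
    return(presets[[regime]])
  }
  stop("regime must be a climate_regime or a preset name")
}

in_windows <- function(doy, windows) {
  hit <- rep(FALSE, length(doy))
  for (w in windows) hit <- hit | (doy >= w[1] & doy <= w[2])
  hit
}

#' Generate a daily weather series
#'
#' Deterministic for a given (regime, years, seed).  The generator uses a
#' private RNG stream and restores the caller's RNG state.
#'
#' @param regime a [climate_regime()] or a preset name.
#' @param years number of 365-day years (>= 1).
#' @param seed integer seed.
#' @return a `data.frame` of class `weather_series` with columns `year`,
#'   `doy`, `date`, `tmax`, `tmin`, `rain`, `solar`, `rh`.
#' @examples
#' wx <- generate_weather("humid", years = 2, seed = 1)
#' summarize_weather(wx)
#' @export
generate_weather <- function(regime, years, seed) {
  regime <- resolve_regime(regime)
  if (!is.numeric(years) || years < 1) stop("years must be >= 1")
  years <- as.integer(years)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))

  ndays <- 365L * years
  year <- rep(seq_len(years), each = 365L)
  doy <- rep(seq_len(365L), times = years)

  # temperature: seasonal sinusoid +/- shared noise, fixed diurnal range
  tm <- regime$mean_temp +
    regime$seasonal_amp * cos(2 * pi * (doy - regime$peak_doy) / 365) +
    stats::rnorm(ndays, 0, regime$temp_sd)
  tmax <- tm + regime$diurnal_range / 2 +
    stats::rnorm(ndays, 0, regime$temp_sd / 2)
  tmin <- tm - regime$diurnal_range / 2 -
    stats::rnorm(ndays, 0, regime$temp_sd / 2)
  swap <- tmin > tmax
  if (any(swap)) {
    tmp <- tmax[swap]; tmax[swap] <- tmin[swap]; tmin[swap] <- tmp
  }

  # rain occurrence: two-state Markov chain, seasonally gated
  inwin <- in_windows(doy, regime$wet_windows)
  p01 <- ifelse(inwin, regime$p_dw, regime$p_dw_off)
  p11 <- ifelse(inwin, regime$p_ww,
                pmin(regime$p_ww, regime$p_dw_off * 2))
  u <- stats::runif(ndays)
  wet <- logical(ndays)
  prev <- FALSE
  for (i in seq_len(ndays)) {
    p <- if (prev) p11[i] else p01[i]
    wet[i] <- u[i] < p
    prev <- wet[i]
  }

  # wet-day amounts: gamma, scale calibrated to the annual target via the
  # stationary wet-day frequency of the chain
  pi_in <- if (regime$p_dw > 0)
    regime$p_dw / (1 + regime$p_dw - regime$p_ww) else 0
  pi_off <- if (regime$p_dw_off > 0)
    regime$p_dw_off / (1 + regime$p_dw_off - min(regime$p_ww,
                                                 regime$p_dw_off * 2)) else 0
  nd_in <- sum(in_windows(seq_len(365L), regime$wet_windows))
  exp_wet <- nd_in * pi_in + (365 - nd_in) * pi_off
  rain <- numeric(ndays)
  if (exp_wet > 0 && regime$annual_rain > 0) {
    scale <- regime$annual_rain / (exp_wet * regime$rain_shape)
    rain[wet] <- stats::rgamma(sum(wet), shape = regime$rain_shape,
                               scale = scale)
  }

  solar <- pmax(0, regime$solar_base + ifelse(wet, regime$solar_wet_adj, 0) +
                  stats::rnorm(ndays, 0, 1))
  rh <- pmin(100, pmax(0, regime$rh_base +
                         ifelse(wet, regime$rh_wet_adj, 0) +
                         stats::rnorm(ndays, 0, 4)))

  ref <- as.Date(paste0(2000 + year, "-01-01")) + (doy - 1L)
  out <- data.frame(year = year, doy = doy, date = format(ref, "%Y-%m-%d"),
                    tmax = tmax, tmin = tmin, rain = rain,
                    solar = solar, rh = rh, stringsAsFactors = FALSE)
  class(out) <- c("weather_series", "data.frame")
  attr(out, "regime") <- regime$name
  out
}

#' Annual weather summaries
#'
#' @param series a `weather_series` (whole 365-day years required).
#' @return data.frame with one row per year: `year`, `rain_mm` (annual
#'   total) and `tmean_c` (mean of the daily midpoint temperature).
#' @export
summarize_weather <- function(series) {
  cnt <- table(series$year)
  bad <- names(cnt)[cnt != 365L]
  if (length(bad))
    stop("summarize_weather: partial year(s): ", paste(bad, collapse = ", "))
  tmid <- (series$tmax + series$tmin) / 2
  out <- data.frame(
    year = as.integer(names(cnt)),
    rain_mm = as.numeric(tapply(series$rain, series$year, sum)),
    tmean_c = as.numeric(tapply(tmid, series$year, mean))
  )
  out[order(out$year), , drop = FALSE]
}

#' Write / read a weather series as CSV
#'
#' Columns `date` (ISO-8601), `tmax_c`, `tmin_c`, `rain_mm`,
#' `solar_mj_m2`, `rh_pct`; one row per day, header required.
#'
#' @param series a `weather_series`.
#' @param path file path.
#' @return `read_weather_csv` returns a `weather_series`.
#' @export
write_weather_csv <- function(series, path) {
  out <- data.frame(date = series$date, tmax_c = series$tmax,
                    tmin_c = series$tmin, rain_mm = series$rain,
                    solar_mj_m2 = series$solar, rh_pct = series$rh)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmax_c", "tmin_c", "rain_mm", "solar_mj_m2", "rh_pct")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("weather CSV missing column(s): ", paste(miss, collapse = ", "))
  d <- as.Date(raw$date)
  yr <- as.integer(format(d, "%Y")) - 2000L
  doy <- as.integer(format(d, "%j"))
  out <- data.frame(year = yr, doy = doy, date = raw$date,
                    tmax = raw$tmax_c, tmin = raw$tmin_c, rain = raw$rain_mm,
                    solar = raw$solar_mj_m2, rh = raw$rh_pct,
                    stringsAsFactors = FALSE)
  class(out) <- c("weather_series", "data.frame")
  out
}
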