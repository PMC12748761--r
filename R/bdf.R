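#' Biodemographic functions (BDFs)
#'
#' Shared temperature/resource response functions used by every species in
#' the cassava system: a unimodal nonlinear developmental rate, degree-day
#' accumulation over a sine-interpolated diurnal temperature path, the
#' demand-driven functional response for resource acquisition, unimodal
#' scalars for temperature (and rain/humidity for fungal pathogens), an
#' age-specific reproductive profile, and a U-shaped temperature-dependent
#' mortality rate.
#'
#' @name bdf
NULL

#' Developmental-rate parameters
#'
#' Parameters of the unimodal nonlinear developmental-rate curve: zero at
#' and below the lower threshold `T0`, zero at and above the upper cutoff
#' `Tmax`, and maximal exactly at the optimum `Topt`.  The curve is the
#' beta-family form \eqn{r(T) = r_{max} u^q v^{q(Tmax-Topt)/(Topt-T0)}}
#' with \eqn{u = (T-T0)/(Topt-T0)} and \eqn{v = (Tmax-T)/(Tmax-Topt)},
#' which rises slowly from the threshold and drops sharply toward the
#' upper cutoff, capturing the limiting effect of high temperature.
#'
#' @param T0 lower developmental threshold, degrees C (cassava 14.86).
#' @param Topt optimum temperature, degrees C.
#' @param Tmax upper cutoff, degrees C.
#' @param q shape exponent (> 0); larger values flatten the low-T rise.
#' @param rmax rate at the optimum, proportion of stage development per day.
#' @return an object of class `dev_rate_params`.
#' @examples
#' p <- dev_rate_params(14.86, 28, 40)
#' dev_rate(c(10, 14.86, 28, 40, 45), p)
#' @export
dev_rate_params <- function(T0, Topt, Tmax, q = 2, rmax = 1) {
  stopifnot(is.numeric(T0), is.numeric(Topt), is.numeric(Tmax))
  if (!(T0 < Topt && Topt < Tmax))
    stop("dev_rate_params: need T0 < Topt < Tmax, got ",
         T0, ", ", Topt, ", ", Tmax)
  if (q <= 0) stop("dev_rate_params: shape q must be > 0")
  if (rmax <= 0) stop("dev_rate_params: rmax must be > 0")
  structure(list(T0 = T0, Topt = Topt, Tmax = Tmax, q = q, rmax = rmax),
            class = "dev_rate_params")
}

#' Temperature-dependent developmental rate
#'
#' @param temp temperature(s), degrees C.  Vectorised.
#' @param p a [dev_rate_params()] object.
#' @return proportion of stage development per day, 0 outside (T0, Tmax).
#' @export
dev_rate <- function(temp, p) {
  u <- (temp - p$T0) / (p$Topt - p$T0)
  v <- (p$Tmax - temp) / (p$Tmax - p$Topt)
  r <- ifelse(temp <= p$T0 | temp >= p$Tmax, 0,
              p$rmax * u^p$q * v^(p$q * (p$Tmax - p$Topt) / (p$Topt - p$T0)))
  r
}

#' Daily physiological time (degree-days) from a sine diurnal path
#'
#' Integrates the normalised nonlinear developmental rate over a 24-point
#' sine interpolation between the day's minimum and maximum temperature and
#' rescales so that a full day at the optimum accumulates `Topt - T0`
#' degree-days (the linear degree-day value at the optimum).  A constant
#' day therefore yields exactly the rescaled rate at that temperature, and
#' a day spent entirely at or below the threshold yields 0.
#'
#' @param tmax,tmin daily extremes, degrees C (`tmin <= tmax`). Vectorised.
#' @param p a [dev_rate_params()] object.
#' @return degree-days above the species threshold for the day.
#' @export
daily_physio_time <- function(tmax, tmin, p) {
  if (any(tmin > tmax)) stop("daily_physio_time: tmin > tmax")
  hours <- (seq_len(24) - 0.5) / 24            # mid-points of 24 hourly bins
  wave <- -cos(2 * pi * hours)                 # -1 at midnight, +1 at noon
  mid <- (tmax + tmin) / 2
  amp <- (tmax - tmin) / 2
  scale <- (p$Topt - p$T0) / p$rmax
  if (length(tmax) == 1L) {
    th <- mid + amp * wave
    return(mean(dev_rate(th, p)) * scale)
  }
  vapply(seq_along(tmax), function(i) {
    th <- mid[i] + amp[i] * wave
    mean(dev_rate(th, p)) * scale
  }, numeric(1))
}

#' Functional response for resource acquisition
#'
#' Demand-driven (ratio-dependent) exponential functional response:
#' \eqn{S = D (1 - e^{-\alpha R / D})}.  The realised supply `S` is always
#' strictly below the demand `D` for finite resource, and never exceeds
#' `alpha * R`, so the supply/demand ratio used downstream to gate growth,
#' fecundity, survival and emigration lies in `[0, 1)`.
#'
#' @param D per-capita-summed demand, resource units per day (> 0).
#' @param R available resource, same units (>= 0).
#' @param alpha apparency/search rate in (0, 1].
#' @return supply `S`, same units as `D`.
#' @examples
#' acquisition(1, 2, 0.5)   # 1 - exp(-1)
#' @export
acquisition <- function(D, R, alpha) {
  if (any(D <= 0)) stop("acquisition: demand D must be > 0")
  if (any(R < 0)) stop("acquisition: resource R must be >= 0")
  if (any(alpha <= 0 | alpha > 1)) stop("acquisition: alpha must be in (0, 1]")
  D * (1 - exp(-alpha * R / D))
}

#' Unimodal scalar parameters
#'
#' A symmetric parabolic scalar in `[0, 1]`: 1 at the optimum, 0 at and
#' beyond the bounds, used to correct reproduction (and other rates) away
#' from the optimum temperature.  `floor` (default 0) is a lower clamp
#' applied inside the bounds.
#'
#' @param lower,opt,upper bounds and optimum of the driving variable.
#' @param floor minimum value inside the bounds, in `[0, 1]`.
#' @export
scalar_params <- function(lower, opt, upper, floor = 0) {
  if (!(lower < opt && opt < upper))
    stop("scalar_params: need lower < opt < upper, got ",
         lower, ", ", opt, ", ", upper)
  if (floor < 0 || floor > 1) stop("scalar_params: floor must be in [0, 1]")
  structure(list(lower = lower, opt = opt, upper = upper, floor = floor),
            class = "scalar_params")
}

#' Unimodal temperature scalar
#'
#' @param temp driving variable value(s).
#' @param p a [scalar_params()] object.
#' @return value(s) in `[0, 1]`; 1 at the optimum, 0 at/beyond the bounds.
#' @export
temp_scalar <- function(temp, p) {
  half <- ifelse(temp < p$opt, p$opt - p$lower, p$upper - p$opt)
  z <- (temp - p$opt) / half
  s <- pmax(0, 1 - z^2)
  ifelse(s > 0, pmax(p$floor, s), 0)
}

#' Mortality-rate parameters
#'
#' Quadratic-limb daily mortality: minimum `mu_min` at the optimum,
#' increasing as `c_cold (opt - T)^2` below and `c_heat (T - opt)^2` above.
#'
#' @param mu_min minimum per-capita rate, per day (>= 0).
#' @param opt temperature of minimum mortality, degrees C.
#' @param c_cold,c_heat curvature constants (>= 0) for the two limbs.
#' @export
mortality_params <- function(mu_min, opt, c_cold, c_heat) {
  if (mu_min < 0 || c_cold < 0 || c_heat < 0)
    stop("mortality_params: rates and curvatures must be >= 0")
  structure(list(mu_min = mu_min, opt = opt, c_cold = c_cold, c_heat = c_heat),
            class = "mortality_params")
}

#' Temperature-dependent per-capita mortality rate
#'
#' @param temp temperature(s), degrees C.
#' @param p a [mortality_params()] object.
#' @return deaths per individual per day (>= `mu_min`).
#' @export
mortality_rate <- function(temp, p) {
  d <- temp - p$opt
  p$mu_min + ifelse(d < 0, p$c_cold * d^2, p$c_heat * d^2)
}

#' Pathogen infection scalar from rainfall and humidity
#'
#' Rain-driven multiplier in `[0, 1]` for fungal epizootics: a saturating
#' Michaelis-type term in trailing rainfall (0.5 at `half_rain`) times a
#' linear ramp in relative humidity between `rh_lo` and `rh_hi`.  Zero at
#' zero rain or below the humidity floor; saturates toward 1 when both
#' drivers are high.
#'
#' @param rain rainfall over the trailing window, mm (>= 0).
#' @param rh relative humidity, percent.
#' @param half_rain rainfall (mm) at which the rain term is 0.5.
#' @param rh_lo,rh_hi humidity ramp bounds, percent.
#' @return infection multiplier in `[0, 1]`.
#' @export
pathogen_scalar <- function(rain, rh, half_rain = 15, rh_lo = 40, rh_hi = 90) {
  if (any(rain < 0)) stop("pathogen_scalar: rain must be >= 0")
  s_rain <- rain / (rain + half_rain)
  s_rh <- pmin(1, pmax(0, (rh - rh_lo) / (rh_hi - rh_lo)))
  s_rain * s_rh
}

#' Age-specific reproduction profile
#'
#' Unimodal per-female oviposition profile over physiological age at the
#' optimum temperature: zero before the age of first reproduction, rising
#' to `peak` at `first + shape` degree-days, then declining
#' (\eqn{peak \cdot x e^{1-x}}, \eqn{x = (a - first)/shape}).
#'
#' @param first physiological age (dd) at first reproduction (>= 0).
#' @param peak maximum rate, eggs per female per day (> 0).
#' @param shape age scale (dd) from first reproduction to the peak (> 0).
#' @export
reproduction_profile <- function(first, peak, shape) {
  if (first < 0 || peak <= 0 || shape <= 0)
    stop("reproduction_profile: need first >= 0, peak > 0, shape > 0")
  structure(list(first = first, peak = peak, shape = shape),
            class = "reproduction_profile")
}

#' Evaluate a reproduction profile at a physiological age
#'
#' @param age physiological age(s), dd since adult emergence.
#' @param profile a [reproduction_profile()] object.
#' @return eggs per female per day at the optimum temperature.
#' @export
reproduction_rate <- function(age, profile) {
  x <- (age - profile$first) / profile$shape
  ifelse(x <= 0, 0, profile$peak * x * exp(1 - x))
}

#' Realised per-female fecundity
#'
#' Product of the age-specific profile, the temperature scalar, and the
#' supply/demand ratio: any one of them at zero gates reproduction off.
#'
#' @param age physiological age(s), dd.
#' @param temp temperature, degrees C.
#' @param sd_ratio supply/demand ratio in `[0, 1]`.
#' @param profile a [reproduction_profile()] object.
#' @param ts a [scalar_params()] object for the temperature correction.
#' @return eggs per female per day.
#' @export
fecundity <- function(age, temp, sd_ratio, profile, ts) {
  if (any(sd_ratio < 0 | sd_ratio > 1))
    stop("fecundity: sd_ratio must be in [0, 1]")
  reproduction_rate(age, profile) * temp_scalar(temp, ts) * sd_ratio
}
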