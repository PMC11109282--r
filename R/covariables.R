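# The 19 agroclimatic covariables: nine raw weather variables passed
# through, plus ten eco-physiological quantities derived with FAO-56
# conventions and Priestley-Taylor potential evapotranspiration.

#' Saturation vapour pressure (Tetens / FAO-56)
#'
#' `es(T) = 0.6108 * exp(17.27 T / (T + 237.3))`, kPa.
#'
#' @param t Air temperature, degrees C (vectorized).
#' @return Saturation vapour pressure, kPa.
#' @export
#' @examples
#' sat_vapour_pressure(0)    # 0.6108
#' sat_vapour_pressure(20)   # ~2.338
sat_vapour_pressure <- function(t) {
  stopifnot(all(t > -50))
  0.6108 * exp(17.27 * t / (t + 237.3))
}

#' Daily vapour pressure deficit
#'
#' `VPD = (es(Tmax) + es(Tmin))/2 - es(Tdew)`, floored at 0. Saturation
#' pressure is averaged over the daily extremes (FAO-56); actual vapour
#' pressure is taken at the dew point.
#'
#' @param tmax,tmin Daily maximum and minimum temperature, degrees C.
#' @param tdew Dew-point temperature, degrees C.
#' @return VPD, kPa (>= 0).
#' @export
vpd_daily <- function(tmax, tmin, tdew) {
  stopifnot(all(tmax >= tmin))
  pmax(0, (sat_vapour_pressure(tmax) + sat_vapour_pressure(tmin)) / 2 -
         sat_vapour_pressure(tdew))
}

#' Slope of the saturation vapour pressure curve
#'
#' `Delta = 4098 es(T) / (T + 237.3)^2`, kPa per degree C.
#'
#' @param t Mean air temperature, degrees C.
#' @return Slope, kPa/degC.
#' @export
slope_svp <- function(t) {
  4098 * sat_vapour_pressure(t) / (t + 237.3)^2
}

#' Daily growing degree-days
#'
#' `GDD = max(0, (Tmax + Tmin)/2 - t_base)`.
#'
#' @param tmax,tmin Daily extremes, degrees C.
#' @param t_base Base temperature, degrees C (default 10, soybean).
#' @return Degree-days (>= 0).
#' @export
gdd_daily <- function(tmax, tmin, t_base = 10) {
  stopifnot(all(tmax >= tmin))
  pmax(0, (tmax + tmin) / 2 - t_base)
}

#' Cardinal temperatures for the FRUE trapezoid
#'
#' Defaults are standard soybean values: base 8, optimum plateau 25-35,
#' ceiling 44 degrees C.
#'
#' @param t_base,t_opt1,t_opt2,t_ceil Cardinal temperatures, degrees C,
#'   with `t_base < t_opt1 <= t_opt2 < t_ceil`.
#' @return A `cardinal_temps` list.
#' @export
cardinal_temps <- function(t_base = 8, t_opt1 = 25, t_opt2 = 35,
                           t_ceil = 44) {
  if (!(t_base < t_opt1 && t_opt1 <= t_opt2 && t_opt2 < t_ceil)) {
    stop("cardinal temperatures must satisfy t_base < t_opt1 <= t_opt2 < t_ceil",
         call. = FALSE)
  }
  structure(list(t_base = t_base, t_opt1 = t_opt1, t_opt2 = t_opt2,
                 t_ceil = t_ceil), class = "cardinal_temps")
}

#' Temperature limitation factor on radiation use efficiency (FRUE)
#'
#' Piecewise-linear trapezoid over the cardinal temperatures: 0 below base
#' and above ceiling, rising linearly to 1 at the lower optimum, 1 across
#' the optimum plateau, falling linearly to 0 at the ceiling.
#'
#' @param t Mean air temperature, degrees C (vectorized).
#' @param cardinals A [cardinal_temps()] object.
#' @return FRUE in `[0, 1]`.
#' @export
frue_daily <- function(t, cardinals = cardinal_temps()) {
  stopifnot(inherits(cardinals, "cardinal_temps"))
  up <- (t - cardinals$t_base) / (cardinals$t_opt1 - cardinals$t_base)
  down <- (cardinals$t_ceil - t) / (cardinals$t_ceil - cardinals$t_opt2)
  pmax(0, pmin(1, pmin(up, down)))
}

solar_declination <- function(doy) 0.409 * sin(2 * pi * doy / 365 - 1.39)

sunset_hour_angle <- function(lat, doy) {
  if (any(abs(lat) >= 66.5)) {
    stop("polar latitudes (|lat| >= 66.5) are not supported", call. = FALSE)
  }
  phi <- lat * pi / 180
  acos(pmin(1, pmax(-1, -tan(phi) * tan(solar_declination(doy)))))
}

#' Daylight hours from latitude and Julian day
#'
#' `N = (24/pi) * omega_s` with sunset hour angle
#' `omega_s = arccos(-tan(phi) tan(delta))` and solar declination
#' `delta = 0.409 sin(2 pi doy/365 - 1.39)` (FAO-56).
#'
#' @param lat Latitude, degrees (|lat| < 66.5).
#' @param doy Julian day of year, 1-365.
#' @return Daylight hours in `[0, 24]`.
#' @export
#' @examples
#' daylight_hours(0, 100)  # 12 at the equator
daylight_hours <- function(lat, doy) {
  24 / pi * sunset_hour_angle(lat, doy)
}

#' Extraterrestrial radiation from latitude and Julian day
#'
#' FAO-56 daily top-of-atmosphere radiation:
#' `Ra = (24*60/pi) * 0.0820 * dr * (omega_s sin(phi) sin(delta) +
#'  cos(phi) cos(delta) sin(omega_s))` with inverse relative Earth-Sun
#' distance `dr = 1 + 0.033 cos(2 pi doy/365)`.
#'
#' @inheritParams daylight_hours
#' @return Radiation, MJ m-2 day-1 (>= 0).
#' @export
extraterrestrial_radiation <- function(lat, doy) {
  phi <- lat * pi / 180
  delta <- solar_declination(doy)
  ws <- sunset_hour_angle(lat, doy)
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  pmax(0, 24 * 60 / pi * 0.0820 * dr *
         (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws)))
}

#' Actual sunshine duration from shortwave radiation (inverted Angstrom)
#'
#' Inverts the Angstrom-Prescott relation `SW/Ra = a_s + b_s n/N`:
#' `n = N ((SW/Ra) - a_s) / b_s`, clamped to `[0, N]`.
#'
#' @param sw Surface shortwave radiation, MJ m-2 day-1.
#' @param rta Extraterrestrial radiation, MJ m-2 day-1 (> 0).
#' @param big_n Daylight hours.
#' @param a_s,b_s Angstrom coefficients (FAO-56 defaults 0.25, 0.50).
#' @return Sunshine hours in `[0, N]`.
#' @export
sunshine_hours <- function(sw, rta, big_n, a_s = 0.25, b_s = 0.50) {
  if (any(rta <= 0)) stop("RTA must be > 0 to invert the Angstrom relation",
                          call. = FALSE)
  pmin(big_n, pmax(0, big_n * ((sw / rta) - a_s) / b_s))
}

#' Priestley-Taylor daily potential evapotranspiration
#'
#' `ETP = alpha * Delta/(Delta + gamma) * Rn / lambda` with net radiation
#' simplified to `Rn = (1 - albedo) SW`. Floored at 0.
#'
#' @param t2m Mean air temperature, degrees C (drives `Delta`).
#' @param sw Surface shortwave radiation, MJ m-2 day-1.
#' @param alpha Priestley-Taylor coefficient (1.26).
#' @param gamma Psychrometric constant, kPa/degC (0.0665).
#' @param lambda Latent heat of vaporization, MJ/kg (2.45).
#' @param albedo Surface albedo (0.23, reference crop).
#' @return ETP, mm day-1 (>= 0).
#' @export
etp_daily <- function(t2m, sw, alpha = 1.26, gamma = 0.0665,
                      lambda = 2.45, albedo = 0.23) {
  stopifnot(all(sw >= 0))
  delta <- slope_svp(t2m)
  pmax(0, alpha * delta / (delta + gamma) * (1 - albedo) * sw / lambda)
}

#' Compute the full 19-covariable panel from a daily weather series
#'
#' Takes one site's daily weather in the NASA-POWER dialect and returns all
#' 19 covariables per day: the nine raw variables (renamed to their
#' covariable codes) plus GDD, FRUE, Trange, VPD, SPV, ETP, PETP, n, N and
#' RTA. Day-of-year 366 is treated as 365 in the astronomical formulas.
#'
#' @param weather Daily weather tibble for a single site with columns
#'   `DATE`, `T2M`, `T2M_MAX`, `T2M_MIN`, `PRECTOTCORR`, `WS2M`, `RH2M`,
#'   `T2MDEW`, `ALLSKY_SFC_LW_DWN`, `ALLSKY_SFC_SW_DWN` (and optionally
#'   `SITE`).
#' @param lat Site latitude, degrees.
#' @param cardinals [cardinal_temps()] for FRUE.
#' @param t_base GDD base temperature, degrees C.
#' @param a_s,b_s Angstrom coefficients for sunshine hours.
#' @param alpha,gamma,lambda,albedo Priestley-Taylor constants.
#' @return Tibble with `SITE`, `DATE`, `YEAR` and the 19 covariable
#'   columns `T2M`, `Tmax`, `Tmin`, `PRECTOT`, `WSM`, `RH`, `TMDEW`, `LW`,
#'   `SW`, `GDD`, `FRUE`, `Trange`, `VPD`, `SPV`, `ETP`, `PETP`, `n`, `N`,
#'   `RTA`.
#' @export
compute_panel <- function(weather, lat, cardinals = cardinal_temps(),
                          t_base = 10, a_s = 0.25, b_s = 0.50,
                          alpha = 1.26, gamma = 0.0665, lambda = 2.45,
                          albedo = 0.23) {
  required <- c("DATE", "T2M", "T2M_MAX", "T2M_MIN", "PRECTOTCORR",
                "WS2M", "RH2M", "T2MDEW", "ALLSKY_SFC_LW_DWN",
                "ALLSKY_SFC_SW_DWN")
  missing_cols <- setdiff(required, names(weather))
  if (length(missing_cols) > 0) {
    stop("weather input lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(weather$DATE, strictly = TRUE)) {
    stop("weather dates must be strictly increasing", call. = FALSE)
  }
  doy <- pmin(365L, as.integer(strftime(weather$DATE, "%j")))
  big_n <- daylight_hours(lat, doy)
  rta <- extraterrestrial_radiation(lat, doy)
  etp <- etp_daily(weather$T2M, weather$ALLSKY_SFC_SW_DWN, alpha = alpha,
                   gamma = gamma, lambda = lambda, albedo = albedo)
  tibble::tibble(
    SITE = if ("SITE" %in% names(weather)) weather$SITE else NA_character_,
    DATE = weather$DATE,
    YEAR = as.integer(strftime(weather$DATE, "%Y")),
    T2M = weather$T2M,
    Tmax = weather$T2M_MAX,
    Tmin = weather$T2M_MIN,
    PRECTOT = weather$PRECTOTCORR,
    WSM = weather$WS2M,
    RH = weather$RH2M,
    TMDEW = weather$T2MDEW,
    LW = weather$ALLSKY_SFC_LW_DWN,
    SW = weather$ALLSKY_SFC_SW_DWN,
    GDD = gdd_daily(weather$T2M_MAX, weather$T2M_MIN, t_base),
    FRUE = frue_daily(weather$T2M, cardinals),
    Trange = weather$T2M_MAX - weather$T2M_MIN,
    VPD = vpd_daily(weather$T2M_MAX, weather$T2M_MIN, weather$T2MDEW),
    SPV = slope_svp(weather$T2M),
    ETP = etp,
    PETP = weather$PRECTOTCORR - etp,
    n = sunshine_hours(weather$ALLSKY_SFC_SW_DWN, rta, big_n, a_s, b_s),
    N = big_n,
    RTA = rta
  )
}

#' Names of the 19 environmental covariables
#' @return Character vector of covariable codes.
#' @export
covariable_names <- function() {
  c("T2M", "Tmax", "Tmin", "PRECTOT", "WSM", "RH", "TMDEW", "LW", "SW",
    "GDD", "FRUE", "Trange", "VPD", "SPV", "ETP", "PETP", "n", "N", "RTA")
}
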