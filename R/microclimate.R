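#' Site description with monthly climate normals
#'
#' Location, measurement height and monthly normals driving the hourly
#' microclimate generator. Normals are user-supplied (e.g. station normals
#' for the site); one row per available month.
#'
#' @param latitude,longitude Decimal degrees (latitude in `[-90, 90]`).
#' @param elevation Metres above sea level (used for the pressure-corrected
#'   optical air mass and the site air pressure).
#' @param reference_height Height (m) the air-temperature and wind normals
#'   refer to; default 1.2 m, a typical within-canopy sampling height.
#' @param normals Data frame with columns `month` (1-12), `t_min`, `t_max`
#'   (degC), `wind_mean` (m s-1), `rh_mean` (percent) and `cloud_fraction`
#'   (0-1).
#' @param transmittance Clear-sky atmospheric transmittance used for the
#'   beam radiation (typical range 0.6-0.75).
#' @return An object of class `site_spec`.
#' @export
site_spec <- function(latitude, longitude = 0, elevation = 0,
                      reference_height = 1.2, normals,
                      transmittance = 0.70) {
  check_number(latitude, "latitude")
  if (latitude < -90 || latitude > 90) {
    abort_field("latitude", "must be in [-90, 90]")
  }
  check_number(elevation, "elevation")
  check_number(reference_height, "reference_height")
  check_number(transmittance, "transmittance")
  req <- c("month", "t_min", "t_max", "wind_mean", "rh_mean",
           "cloud_fraction")
  if (!is.data.frame(normals) || !all(req %in% names(normals))) {
    abort_field("normals", paste("must have columns",
                                 paste0("`", req, "`", collapse = ", ")))
  }
  if (any(normals$t_min > normals$t_max)) {
    abort_field("normals", "t_min must not exceed t_max")
  }
  if (any(normals$cloud_fraction < 0 | normals$cloud_fraction > 1)) {
    abort_field("normals", "cloud_fraction must be in [0, 1]")
  }
  structure(
    list(
      latitude = latitude, longitude = longitude, elevation = elevation,
      reference_height = reference_height,
      normals = normals[req],
      transmittance = transmittance
    ),
    class = "site_spec"
  )
}

#' Warming scenario as additive monthly air-temperature deltas
#'
#' @param name Scenario label.
#' @param delta Either a single degC offset applied to every month or a
#'   length-12 vector of monthly offsets.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, delta = 0) {
  if (!is.numeric(delta) || !(length(delta) %in% c(1L, 12L)) ||
      any(!is.finite(delta))) {
    abort_field("delta", "must be a finite scalar or length-12 vector")
  }
  structure(
    list(name = as.character(name),
         delta = if (length(delta) == 1L) rep(delta, 12L) else delta),
    class = "scenario_spec"
  )
}

# solar declination (degrees), Cooper's formula
solar_declination <- function(day_of_year) {
  23.45 * sin(2 * pi * (284 + day_of_year) / 365)
}

#' Solar zenith angle
#'
#' Zenith angle from standard declination (Cooper's formula) and hour-angle
#' geometry; hours are local solar time with solar noon at hour 12.
#'
#' @param latitude Decimal degrees.
#' @param day_of_year Day of year (1-365).
#' @param hour Local solar hour (0-24, fractional allowed).
#' @return Zenith angle in degrees (0 = overhead, > 90 = below horizon).
#' @examples
#' solar_position(47.52, 172, 12)  # near-solstice solar noon
#' @export
solar_position <- function(latitude, day_of_year, hour) {
  check_number(latitude, "latitude")
  decl <- solar_declination(day_of_year) * pi / 180
  lat <- latitude * pi / 180
  ha <- (hour - 12) * 15 * pi / 180
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  acos(pmin(pmax(cosz, -1), 1)) * 180 / pi
}

# sunrise/sunset hours in local solar time; NULL components signal polar
# night (no sunrise) or polar day (no sunset)
sun_hours <- function(latitude, day_of_year) {
  decl <- solar_declination(day_of_year) * pi / 180
  lat <- latitude * pi / 180
  arg <- -tan(lat) * tan(decl)
  if (arg >= 1) {
    list(sunrise = NA_real_, sunset = NA_real_, polar = "night")
  } else if (arg <= -1) {
    list(sunrise = 0, sunset = 24, polar = "day")
  } else {
    h0 <- acos(arg) * 180 / pi / 15
    list(sunrise = 12 - h0, sunset = 12 + h0, polar = "none")
  }
}

#' Diurnal air-temperature interpolation from daily extremes
#'
#' Sine-exponential diurnal scheme: during the day the temperature follows
#' a sine from `t_min` at sunrise to `t_max` at `peak_lag` hours after
#' solar noon; at night it decays exponentially from the sunset temperature
#' back to `t_min` at the next sunrise. The night branch is rescaled so
#' both junctions are exact, making the 24-h curve continuous and the
#' stated extremes attained exactly once each.
#'
#' @param t_min,t_max Daily minimum and maximum air temperature (degC).
#' @param hour Local solar hour (fractional allowed; vectorised).
#' @param sunrise_hour,sunset_hour Sunrise and sunset in local solar hours.
#' @param peak_lag Hours after solar noon at which `t_max` occurs.
#' @param night_coef Dimensionless nocturnal decay coefficient.
#' @return Air temperature(s), degC.
#' @export
hourly_air_temperature <- function(t_min, t_max, hour,
                                   sunrise_hour = 6, sunset_hour = 18,
                                   peak_lag = 1.5, night_coef = 2.2) {
  check_number(t_min, "t_min")
  check_number(t_max, "t_max")
  if (t_min > t_max) abort_field("t_min", "must not exceed t_max")
  if (t_min == t_max) return(rep(t_min, length(hour)))
  if (is.na(sunrise_hour) || is.na(sunset_hour)) {
    # sun never rises: no diurnal forcing, hold the midpoint
    return(rep((t_min + t_max) / 2, length(hour)))
  }
  dl <- sunset_hour - sunrise_hour
  nl <- 24 - dl
  # half-period spans sunrise to (solar noon + peak_lag)
  per <- dl + 2 * peak_lag
  day_t <- function(t) {
    t_min + (t_max - t_min) * sin(pi * (t - sunrise_hour) / per)
  }
  t_sunset <- day_t(sunset_hour)
  night_t <- function(n) {
    if (nl <= 0) return(rep(t_min, length(n)))
    decay <- (exp(-night_coef * n / nl) - exp(-night_coef)) /
      (1 - exp(-night_coef))
    t_min + (t_sunset - t_min) * decay
  }
  vapply(hour, function(h) {
    if (h >= sunrise_hour && h <= sunset_hour) {
      day_t(h)
    } else {
      n_since <- if (h > sunset_hour) h - sunset_hour else
        h + 24 - sunset_hour
      night_t(n_since)
    }
  }, numeric(1))
}

# partition solar radiation at one hour into direct and diffuse horizontal
# components (W m-2), given zenith (deg), day, cloud fraction, elevation
solar_fluxes <- function(zenith, day_of_year, cloud_fraction, elevation,
                         transmittance) {
  if (zenith >= 90) {
    return(c(direct = 0, diffuse = 0, extraterrestrial = 0))
  }
  cosz <- cos(zenith * pi / 180)
  s0 <- 1361 * (1 + 0.033 * cos(2 * pi * day_of_year / 365))
  m <- exp(-elevation / 8200) / cosz
  beam_h <- s0 * transmittance^m * cosz
  diff_clear <- 0.3 * (1 - transmittance^m) * s0 * cosz
  total_clear <- beam_h + diff_clear
  # cloud attenuation of the total (Kasten-Czeplak form) and a diffuse
  # share growing linearly with cloud cover
  total <- total_clear * (1 - 0.75 * cloud_fraction^3)
  fd_clear <- if (total_clear > 0) diff_clear / total_clear else 1
  fd <- fd_clear + (1 - fd_clear) * cloud_fraction
  c(direct = total * (1 - fd), diffuse = total * fd,
    extraterrestrial = s0 * cosz)
}

# effective sky temperature (degC) from air temperature, vapour pressure
# and cloud: Brutsaert clear-sky emissivity blended with cloud
sky_temperature <- function(air_c, vp_pa, cloud_fraction) {
  t_k <- celsius_to_kelvin(air_c)
  eps_clear <- 1.72 * (vp_pa / 1000 / t_k)^(1 / 7)
  eps <- (1 - 0.84 * cloud_fraction) * eps_clear + 0.84 * cloud_fraction
  eps <- pmin(eps, 1)
  t_k * eps^0.25 - 273.15
}

mid_month_day <- function(month) {
  cumdays <- c(0, cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30)))
  cumdays[month] + 15
}

#' Hourly microclimate for the middle day of a month
#'
#' Generates 24 hourly rows of air temperature, direct and diffuse solar
#' radiation, wind, relative humidity, sky temperature and solar zenith for
#' the mid-day of a month from the site's monthly normals. Air temperature
#' follows the sine-exponential diurnal scheme between the month's normal
#' extremes; solar radiation is clear-sky beam/diffuse attenuated by the
#' monthly cloud fraction; relative humidity assumes a day-constant vapour
#' pressure set by the mean temperature and mean RH; sky temperature uses a
#' clear-sky emissivity formula blended with cloud. A warming scenario adds
#' its monthly delta to air temperature after interpolation (humidity and
#' sky temperature are then computed from the warmed air). Hours are local
#' solar time.
#'
#' @param site A [site_spec()].
#' @param month Month number (1-12); must be present in the site normals.
#' @param scenario A [scenario_spec()] or `NULL` for current climate.
#' @return A data frame (class `microclimate_series`) with columns `hour`,
#'   `air_temperature`, `direct_solar`, `diffuse_solar`, `wind`,
#'   `relative_humidity`, `sky_temperature`, `zenith_angle`; attributes
#'   `month`, `day_of_year`, `scenario` and `pressure` (site air pressure,
#'   Pa).
#' @export
generate_microclimate <- function(site, month, scenario = NULL) {
  stopifnot(inherits(site, "site_spec"))
  month <- check_count(month, "month")
  row <- site$normals[site$normals$month == month, ]
  if (nrow(row) != 1L) {
    abort_field("month", sprintf("no normals available for month %d", month))
  }
  delta <- 0
  sc_name <- "current"
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "scenario_spec"))
    delta <- scenario$delta[month]
    sc_name <- scenario$name
  }
  doy <- mid_month_day(month)
  sun <- sun_hours(site$latitude, doy)
  hours <- 0:23
  zen <- solar_position(site$latitude, doy, hours)
  air <- hourly_air_temperature(row$t_min, row$t_max, hours,
                                sun$sunrise, sun$sunset) + delta
  sol <- t(vapply(zen, solar_fluxes, numeric(3),
                  day_of_year = doy, cloud_fraction = row$cloud_fraction,
                  elevation = site$elevation,
                  transmittance = site$transmittance))
  t_mean <- (row$t_min + row$t_max) / 2 + delta
  vp <- row$rh_mean / 100 * saturation_vp(t_mean)
  rh <- pmin(pmax(100 * vp / saturation_vp(air), 1), 100)
  sky <- sky_temperature(air, vp, row$cloud_fraction)
  out <- data.frame(
    hour = hours,
    air_temperature = air,
    direct_solar = sol[, "direct"],
    diffuse_solar = sol[, "diffuse"],
    wind = rep(row$wind_mean, 24L),
    relative_humidity = rh,
    sky_temperature = sky,
    zenith_angle = zen
  )
  attr(out, "month") <- month
  attr(out, "day_of_year") <- doy
  attr(out, "scenario") <- sc_name
  attr(out, "pressure") <- P_ATM * exp(-site$elevation / 8200)
  class(out) <- c("microclimate_series", "data.frame")
  out
}
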