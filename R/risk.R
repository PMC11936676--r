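#' Thermal risk: hours per day above the upper lethal temperature
#'
#' Counts hours with temperature strictly above `lt50`; if the series spans
#' several days (a multiple of `hours_per_day` values) the count is
#' averaged per day.
#'
#' @param temperatures Hourly temperatures (degC).
#' @param lt50 Upper lethal temperature (degC).
#' @param hours_per_day Hours per simulated day (default 24).
#' @return Hours per day (0 to `hours_per_day`).
#' @export
thermal_risk <- function(temperatures, lt50, hours_per_day = 24L) {
  if (length(temperatures) == 0L) {
    stop("temperature series must be non-empty", call. = FALSE)
  }
  n_days <- max(length(temperatures) / hours_per_day, 1)
  sum(temperatures > lt50) / n_days
}

#' Window of opportunity: hours per day within the preferred band
#'
#' Counts hours with air temperature inside the closed interval
#' `[tpref_mean - tpref_sd, tpref_mean + tpref_sd]`, averaged per day when
#' several days are supplied.
#'
#' @param air_temperatures Hourly air temperatures (degC).
#' @param tpref_mean Preferred temperature (degC).
#' @param tpref_sd Standard deviation of the preference (degC), >= 0.
#' @param hours_per_day Hours per simulated day.
#' @return Hours per day.
#' @export
opportunity_window <- function(air_temperatures, tpref_mean, tpref_sd,
                               hours_per_day = 24L) {
  if (tpref_sd < 0) abort_field("tpref_sd", "must be non-negative")
  if (length(air_temperatures) == 0L) {
    stop("temperature series must be non-empty", call. = FALSE)
  }
  n_days <- max(length(air_temperatures) / hours_per_day, 1)
  inside <- air_temperatures >= tpref_mean - tpref_sd &
    air_temperatures <= tpref_mean + tpref_sd
  sum(inside) / n_days
}

#' Thermal safety margin
#'
#' Upper thermal limit minus the maximum temperature experienced in the
#' organism's microhabitat. Negative values mean the limit is exceeded.
#'
#' @param lt50 Upper lethal temperature (degC).
#' @param max_temperature Maximum microhabitat temperature (degC).
#' @return Margin in degC.
#' @examples
#' safety_margin(42.1, 25.7)
#' safety_margin(37.4, 20.9)
#' @export
safety_margin <- function(lt50, max_temperature) {
  lt50 - max_temperature
}

#' Risk and opportunity metrics per climate scenario
#'
#' For each scenario, simulates the hourly microclimate for the mid-days of
#' the interaction months (May-July by default), solves the sun-exposed
#' leaf energy budget, and computes: host thermal risk on leaf
#' temperatures, parasitoid thermal risk and window of opportunity on air
#' temperatures, safety margins against the respective series maxima, and
#' the maxima themselves. Daily metrics are means over the mid-month days.
#'
#' Hosts (leaf-mining larvae) experience leaf temperature; flying adult
#' parasitoids experience air temperature at the site reference height in
#' the sun.
#'
#' @param site A [site_spec()].
#' @param scenarios List of [scenario_spec()] objects.
#' @param leaf_params_sun [leaf_parameters()] with `exposure = "sun"`.
#' @param lt50_host,lt50_parasitoid Upper lethal temperatures (degC).
#' @param tpref_mean,tpref_sd Parasitoid thermal preference moments (degC).
#' @param months Months to simulate (default May-July).
#' @return A data frame (class `risk_report`), one row per scenario, with
#'   columns `scenario`, `host_thermal_risk`, `parasitoid_thermal_risk`,
#'   `opportunity_window` (hours/day), `host_safety_margin`,
#'   `parasitoid_safety_margin`, `max_leaf_temperature`,
#'   `max_air_temperature` (degC). The per-hour series used are attached as
#'   attribute `hourly` (one data frame per scenario).
#' @export
scenario_report <- function(site, scenarios, leaf_params_sun,
                            lt50_host, lt50_parasitoid,
                            tpref_mean, tpref_sd, months = 5:7) {
  stopifnot(inherits(site, "site_spec"))
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  if (length(scenarios) == 0L) {
    stop("at least one scenario is required", call. = FALSE)
  }
  if (leaf_params_sun$exposure != "sun") {
    abort_field("leaf_params_sun", "must have exposure = \"sun\"")
  }
  rows <- list()
  hourly <- list()
  for (sc in scenarios) {
    series <- lapply(months, function(m) {
      mc <- tryCatch(generate_microclimate(site, m, sc), error = function(e) {
        stop(sprintf("scenario %s, month %d: %s", sc$name, m,
                     conditionMessage(e)), call. = FALSE)
      })
      ls <- leaf_series(mc, leaf_params_sun)
      ls$month <- m
      ls
    })
    all_h <- do.call(rbind, lapply(series, as.data.frame))
    leaf_t <- all_h$leaf_temperature
    air_t <- all_h$air_temperature
    rows[[sc$name]] <- data.frame(
      scenario = sc$name,
      host_thermal_risk = thermal_risk(leaf_t, lt50_host),
      parasitoid_thermal_risk = thermal_risk(air_t, lt50_parasitoid),
      opportunity_window = opportunity_window(air_t, tpref_mean, tpref_sd),
      host_safety_margin = safety_margin(lt50_host, max(leaf_t)),
      parasitoid_safety_margin = safety_margin(lt50_parasitoid, max(air_t)),
      max_leaf_temperature = max(leaf_t),
      max_air_temperature = max(air_t),
      stringsAsFactors = FALSE
    )
    hourly[[sc$name]] <- all_h
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "hourly") <- hourly
  class(out) <- c("risk_report", "data.frame")
  out
}
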