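#' Design of a synthetic acute heat-shock trial
#'
#' Describes a heat-shock survival experiment in which batches of individuals
#' are exposed to a set of shock temperatures and scored dead or alive. The
#' generating model is the logistic dose-response curve that the analysis
#' side fits back: survival probability `plogis(b0 + b * T)` with
#' `b = true_slope` and `b0 = -true_slope * true_lt50`, so that survival is
#' exactly 1/2 at `true_lt50`.
#'
#' The default design mirrors a typical assay on small adult hymenoptera:
#' six shock temperatures from 34 to 44 degC and about seven individuals per
#' temperature.
#'
#' @param shock_temperatures Strictly increasing vector of shock
#'   temperatures (degC).
#' @param n_per_temperature Individuals exposed at each temperature.
#' @param true_lt50 Temperature at which half the individuals die (degC).
#' @param true_slope Logistic slope in logit units per degC; must be
#'   negative (survival declines with temperature).
#' @param species Label attached to every generated record.
#' @param seed Integer seed; generation is a pure function of the design.
#' @return An object of class `heat_shock_design`.
#' @seealso [simulate_heat_shock()], [fit_logistic_survival()]
#' @export
heat_shock_design <- function(shock_temperatures = seq(34, 44, by = 2),
                              n_per_temperature = 7L,
                              true_lt50 = 37.4,
                              true_slope = -0.25,
                              species = "parasitoid",
                              seed = 1L) {
  if (!is.numeric(shock_temperatures) || length(shock_temperatures) < 1L ||
      anyNA(shock_temperatures)) {
    abort_field("shock_temperatures", "must be a non-empty numeric vector")
  }
  if (is.unsorted(shock_temperatures, strictly = TRUE)) {
    abort_field("shock_temperatures", "must be strictly increasing")
  }
  n_per_temperature <- check_count(n_per_temperature, "n_per_temperature")
  check_number(true_lt50, "true_lt50")
  check_number(true_slope, "true_slope")
  if (true_slope >= 0) abort_field("true_slope", "must be negative")
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(
      shock_temperatures = as.numeric(shock_temperatures),
      n_per_temperature = n_per_temperature,
      true_lt50 = true_lt50,
      true_slope = true_slope,
      species = as.character(species),
      seed = seed
    ),
    class = "heat_shock_design"
  )
}

#' Simulate individual heat-shock survival records
#'
#' Each individual at shock temperature `T` survives independently with
#' probability `plogis(b0 + b * T)` where `b` is the design's `true_slope`
#' and `b0 = -true_slope * true_lt50`. Identical designs (including seed)
#' give identical records.
#'
#' @param design A [heat_shock_design()].
#' @return A data frame with columns `individual_id`, `species`,
#'   `shock_temperature` and `survived` (0/1).
#' @examples
#' d <- heat_shock_design(seed = 42)
#' head(simulate_heat_shock(d))
#' @export
simulate_heat_shock <- function(design) {
  stopifnot(inherits(design, "heat_shock_design"))
  b <- design$true_slope
  b0 <- -design$true_slope * design$true_lt50
  temps <- rep(design$shock_temperatures, each = design$n_per_temperature)
  p <- plogis(b0 + b * temps)
  survived <- withr::with_seed(design$seed, rbinom(length(temps), 1L, p))
  data.frame(
    individual_id = sprintf("hs%04d", seq_along(temps)),
    species = design$species,
    shock_temperature = temps,
    survived = survived,
    stringsAsFactors = FALSE
  )
}

#' Design of a synthetic thermal-gradient preference assay
#'
#' Describes a paired control/gradient assay on a linear thermal gradient
#' bar. In the control run (gradient off) individuals settle uniformly over
#' the marked positions; in the gradient run they settle so that the
#' temperature at their position follows a normal preferred-temperature
#' distribution truncated to the bar's temperature range. Positions are
#' discretised to the marked intervals by default, as gradient bars record
#' marked positions rather than continuous locations.
#'
#' Position labels run from 1 at the hot end to `n_positions` at the cold
#' end by default (higher labels = cooler), configurable through the
#' [gradient_spec()] used for mapping.
#'
#' @param n_individuals Number of assayed individuals.
#' @param tpref_mean,tpref_sd Mean and standard deviation (degC) of the
#'   underlying normal preferred-temperature distribution (before
#'   truncation to the bar range).
#' @param rearing_temperatures Rearing (daytime-maximum) temperatures
#'   assigned round-robin across individuals (degC).
#' @param bar_cold_end,bar_hot_end Temperatures at the two ends of the bar
#'   (degC).
#' @param n_positions Number of marked positions along the bar.
#' @param discretize If `TRUE` (default) gradient positions snap to the
#'   nearest mark; if `FALSE` continuous positions are returned.
#' @param seed Integer seed.
#' @return An object of class `gradient_design`.
#' @export
gradient_design <- function(n_individuals = 135L,
                            tpref_mean = 20.1,
                            tpref_sd = 4.5,
                            rearing_temperatures = c(15, 20, 25, 30, 35),
                            bar_cold_end = 12.5,
                            bar_hot_end = 44.5,
                            n_positions = 6L,
                            discretize = TRUE,
                            seed = 1L) {
  n_individuals <- check_count(n_individuals, "n_individuals")
  check_number(tpref_mean, "tpref_mean")
  check_number(tpref_sd, "tpref_sd")
  if (tpref_sd <= 0) abort_field("tpref_sd", "must be positive")
  check_number(bar_cold_end, "bar_cold_end")
  check_number(bar_hot_end, "bar_hot_end")
  if (bar_cold_end >= bar_hot_end) {
    abort_field("bar_cold_end", "must be below bar_hot_end")
  }
  if (tpref_mean < bar_cold_end || tpref_mean > bar_hot_end) {
    abort_field("tpref_mean", "must lie within the bar temperature range")
  }
  n_positions <- check_count(n_positions, "n_positions", min = 2L)
  check_flag(discretize, "discretize")
  seed <- check_count(seed, "seed", min = 0L)
  if (!is.numeric(rearing_temperatures) || length(rearing_temperatures) < 1L) {
    abort_field("rearing_temperatures", "must be a non-empty numeric vector")
  }
  structure(
    list(
      n_individuals = n_individuals,
      tpref_mean = tpref_mean,
      tpref_sd = tpref_sd,
      rearing_temperatures = as.numeric(rearing_temperatures),
      bar_cold_end = bar_cold_end,
      bar_hot_end = bar_hot_end,
      n_positions = n_positions,
      discretize = discretize,
      seed = seed
    ),
    class = "gradient_design"
  )
}

# inverse-CDF sample from Normal(mean, sd) truncated to [lo, hi]
rtruncnorm_inv <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Simulate paired control/gradient trials on a thermal-gradient bar
#'
#' Control positions are uniform over the marked positions. Gradient
#' positions are obtained by sampling a preferred temperature from
#' `Normal(tpref_mean, tpref_sd)` truncated to the bar's range, converting
#' it to a (continuous) position along the bar and, by default, snapping to
#' the nearest mark. Rearing temperatures are assigned round-robin.
#'
#' @param design A [gradient_design()].
#' @return A data frame with columns `individual_id`, `rearing_temperature`,
#'   `position_control` and `position_gradient`.
#' @export
simulate_gradient_trials <- function(design) {
  stopifnot(inherits(design, "gradient_design"))
  n <- design$n_individuals
  spec <- gradient_spec(
    cold_end = design$bar_cold_end, hot_end = design$bar_hot_end,
    n_positions = design$n_positions
  )
  withr::with_seed(design$seed, {
    pos_control <- sample.int(design$n_positions, n, replace = TRUE)
    temps <- rtruncnorm_inv(n, design$tpref_mean, design$tpref_sd,
                            design$bar_cold_end, design$bar_hot_end)
    pos_gradient <- temperature_to_position(temps, spec)
    if (design$discretize) pos_gradient <- round(pos_gradient)
    data.frame(
      individual_id = sprintf("gt%04d", seq_len(n)),
      rearing_temperature =
        rep_len(design$rearing_temperatures, n),
      position_control = as.numeric(pos_control),
      position_gradient = pmin(pmax(pos_gradient, 1), design$n_positions),
      stringsAsFactors = FALSE
    )
  })
}

#' Effective rearing temperature of a square-wave day/night regime
#'
#' Collapses a rearing regime with a daytime maximum and a cooler night to a
#' single photoperiod-weighted mean temperature,
#' `(day_hours * t_day + night_hours * t_night) / 24`. The default 14:10
#' light:dark cycle with 10 degC nights matches a spring rearing protocol
#' for montane insects.
#'
#' @param t_day Daytime maximum temperature (degC).
#' @param t_night Night temperature (degC).
#' @param day_hours Hours per day at `t_day`.
#' @return Effective mean temperature (degC).
#' @export
effective_rearing_temperature <- function(t_day, t_night = 10, day_hours = 14) {
  (day_hours * t_day + (24 - day_hours) * t_night) / 24
}

#' Design of a synthetic emergence (development-time) experiment
#'
#' Emulates rearing parasitised and unparasitised leaves at a set of
#' daytime-maximum temperatures and recording days to adult emergence.
#' Development follows a degree-day model: days to emergence equal the
#' thermal constant `dd` divided by the excess of the effective rearing
#' temperature over the base temperature `t0`, plus Gaussian noise,
#' truncated below at one day. Host and parasitoid have separate degree-day
#' parameters; the defaults make the two mean emergence curves cross
#' between 15 and 35 degC daytime maxima (parasitoids slower than hosts at
#' the coldest rearing temperature, faster at the warmest), the interaction
#' structure typical of differentially temperature-sensitive host and
#' parasitoid development.
#'
#' Each leaf independently yields a host emergence (probability
#' `emergence_probability["host"]`), a parasitoid emergence
#' (`emergence_probability["parasitoid"]`) or nothing.
#'
#' @param rearing_temperatures Daytime maxima (degC).
#' @param n_leaves_per_temperature Leaves per rearing temperature.
#' @param host,parasitoid Named lists with elements `dd` (degree-days above
#'   the base, degC-days), `t0` (base temperature, degC) and `noise_sd`
#'   (days).
#' @param emergence_probability Named numeric vector with elements `host`
#'   and `parasitoid`; their sum must not exceed 1.
#' @param t_night,day_hours Night temperature and photoperiod used to
#'   compute the effective rearing temperature.
#' @param seed Integer seed.
#' @return An object of class `emergence_design`.
#' @export
emergence_design <- function(rearing_temperatures = c(15, 20, 25, 30, 35),
                             n_leaves_per_temperature = 150L,
                             host = list(dd = 250, t0 = 4, noise_sd = 3),
                             parasitoid = list(dd = 165, t0 = 9.5, noise_sd = 3),
                             emergence_probability =
                               c(host = 0.14, parasitoid = 0.36),
                             t_night = 10,
                             day_hours = 14,
                             seed = 1L) {
  if (!is.numeric(rearing_temperatures) || length(rearing_temperatures) < 1L) {
    abort_field("rearing_temperatures", "must be a non-empty numeric vector")
  }
  n_leaves_per_temperature <-
    check_count(n_leaves_per_temperature, "n_leaves_per_temperature")
  for (ty in c("host", "parasitoid")) {
    par <- if (ty == "host") host else parasitoid
    for (f in c("dd", "t0", "noise_sd")) {
      check_number(par[[f]], paste0(ty, "$", f))
    }
    if (par$dd <= 0) abort_field(paste0(ty, "$dd"), "must be positive")
    if (par$noise_sd < 0) {
      abort_field(paste0(ty, "$noise_sd"), "must be non-negative")
    }
  }
  ep <- emergence_probability
  if (is.null(names(ep)) || !all(c("host", "parasitoid") %in% names(ep))) {
    abort_field("emergence_probability", "must name `host` and `parasitoid`")
  }
  if (any(ep < 0) || any(ep > 1) || sum(ep[c("host", "parasitoid")]) > 1) {
    abort_field("emergence_probability",
                "probabilities must be in [0, 1] and sum to at most 1")
  }
  t_eff <- effective_rearing_temperature(rearing_temperatures, t_night,
                                         day_hours)
  for (ty in c("host", "parasitoid")) {
    t0 <- (if (ty == "host") host else parasitoid)$t0
    if (any(t_eff <= t0)) {
      abort_field("rearing_temperatures", sprintf(
        "effective temperature must exceed the %s base temperature (%.3g degC)",
        ty, t0
      ))
    }
  }
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(
      rearing_temperatures = as.numeric(rearing_temperatures),
      n_leaves_per_temperature = n_leaves_per_temperature,
      host = host,
      parasitoid = parasitoid,
      emergence_probability = ep[c("host", "parasitoid")],
      t_night = t_night,
      day_hours = day_hours,
      seed = seed
    ),
    class = "emergence_design"
  )
}

#' Simulate days-to-emergence records under a degree-day model
#'
#' For each leaf an outcome (host emergence, parasitoid emergence, none) is
#' drawn from the design's emergence probabilities; emerging insects get
#' `dd / (t_eff - t0) + Normal(0, noise_sd)` days, truncated at a one-day
#' minimum, where `t_eff` is the photoperiod-weighted effective rearing
#' temperature of their treatment.
#'
#' @param design An [emergence_design()].
#' @return A data frame with columns `insect_type` (`"host"` or
#'   `"parasitoid"`), `rearing_temperature` (daytime max, degC) and
#'   `days_to_emergence`.
#' @export
simulate_emergence <- function(design) {
  stopifnot(inherits(design, "emergence_design"))
  temps <- rep(design$rearing_temperatures,
               each = design$n_leaves_per_temperature)
  ep <- design$emergence_probability
  withr::with_seed(design$seed, {
    u <- runif(length(temps))
    type <- ifelse(u < ep[["host"]], "host",
                   ifelse(u < ep[["host"]] + ep[["parasitoid"]],
                          "parasitoid", NA_character_))
    keep <- !is.na(type)
    type <- type[keep]
    temps <- temps[keep]
    t_eff <- effective_rearing_temperature(temps, design$t_night,
                                           design$day_hours)
    par <- list(host = design$host, parasitoid = design$parasitoid)
    dd <- vapply(type, function(ty) par[[ty]]$dd, numeric(1))
    t0 <- vapply(type, function(ty) par[[ty]]$t0, numeric(1))
    nsd <- vapply(type, function(ty) par[[ty]]$noise_sd, numeric(1))
    days <- dd / (t_eff - t0) + rnorm(length(type), 0, nsd)
    days <- pmax(days, 1)
    data.frame(
      insect_type = type,
      rearing_temperature = temps,
      days_to_emergence = days,
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  })
}
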