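#' Leaf radiative and exchange parameters
#'
#' Parameters of the steady-state leaf energy budget. Defaults describe a
#' broadleaf (aspen-like) leaf: shortwave absorptance 0.5, thermal
#' emissivity 0.97, characteristic dimension 5 cm, stomatal conductance
#' 0.2 mol m-2 s-1, hypostomatous (one transpiring face).
#'
#' @param absorptance Shortwave absorptance (0-1).
#' @param emissivity Thermal (longwave) emissivity (0-1).
#' @param dimension Characteristic leaf dimension d (m), > 0.
#' @param stomatal_conductance Stomatal conductance to water vapour
#'   (mol m-2 s-1), >= 0.
#' @param exposure `"sun"` (direct + diffuse shortwave) or `"shade"`
#'   (diffuse only, as within a canopy).
#' @return An object of class `leaf_parameters`.
#' @export
leaf_parameters <- function(absorptance = 0.5, emissivity = 0.97,
                            dimension = 0.05, stomatal_conductance = 0.2,
                            exposure = c("sun", "shade")) {
  exposure <- match.arg(exposure)
  check_number(absorptance, "absorptance")
  check_number(emissivity, "emissivity")
  check_number(dimension, "dimension")
  check_number(stomatal_conductance, "stomatal_conductance")
  if (absorptance < 0 || absorptance > 1) {
    abort_field("absorptance", "must be in [0, 1]")
  }
  if (emissivity < 0 || emissivity > 1) {
    abort_field("emissivity", "must be in [0, 1]")
  }
  if (dimension <= 0) abort_field("dimension", "must be positive")
  if (stomatal_conductance < 0) {
    abort_field("stomatal_conductance", "must be non-negative")
  }
  structure(
    list(absorptance = absorptance, emissivity = emissivity,
         dimension = dimension,
         stomatal_conductance = stomatal_conductance,
         exposure = exposure),
    class = "leaf_parameters"
  )
}

#' Boundary-layer conductance of a leaf in forced convection
#'
#' `g_bl = 1.4 * 0.135 * sqrt(wind / d)` (mol m-2 s-1, one leaf face), the
#' standard forced-convection form with the 1.4 outdoor-turbulence factor,
#' floored at a free-convection minimum so the conductance never vanishes
#' in still air.
#'
#' @param wind Wind speed (m s-1), >= 0.
#' @param dimension Characteristic leaf dimension (m), > 0.
#' @param floor Free-convection minimum conductance (mol m-2 s-1).
#' @return Conductance, mol m-2 s-1.
#' @export
boundary_layer_conductance <- function(wind, dimension, floor = 0.05) {
  if (any(wind < 0)) abort_field("wind", "must be non-negative")
  if (dimension <= 0) abort_field("dimension", "must be positive")
  pmax(1.4 * 0.135 * sqrt(wind / dimension), floor)
}

#' Solve the steady-state leaf energy budget for one hour
#'
#' Finds the leaf temperature at which absorbed radiation balances emitted
#' thermal radiation, sensible heat exchange and transpirational latent
#' heat:
#' \deqn{R_{abs} = 2\,\epsilon\sigma T_L^4 + c_p g_H (T_L - T_{air})
#'   + \lambda g_v \, (e_s(T_L) - e_a)/P}
#' Absorbed radiation is shortwave (direct + diffuse in the sun, diffuse
#' only in the shade) times the absorptance, plus longwave from the sky on
#' the upper face and from the ground on the lower face. Both faces
#' exchange sensible heat and emit longwave; one face transpires
#' (hypostomatous), with stomatal and boundary-layer conductances in
#' series. The root is found by safeguarded Newton iteration with a
#' bisection fallback inside `[T_air - 20, T_air + 30]`.
#'
#' @param forcing One hour of microclimate: a list or single-row data frame
#'   with `air_temperature`, `direct_solar`, `diffuse_solar`, `wind`,
#'   `relative_humidity` and `sky_temperature`.
#' @param params A [leaf_parameters()].
#' @param ground_temperature Ground temperature (degC) for upward longwave;
#'   defaults to air temperature (no soil model).
#' @param pressure Air pressure (Pa).
#' @param tol Convergence tolerance on the flux residual (W m-2).
#' @param max_iter Iteration cap.
#' @return List with `leaf_temperature` (degC), `excess` (leaf minus air,
#'   degC) and `fluxes` (named vector: `r_abs`, `l_out`, `sensible`,
#'   `latent`, `residual`, all W m-2).
#' @export
solve_leaf_temperature <- function(forcing, params,
                                   ground_temperature = NULL,
                                   pressure = P_ATM,
                                   tol = 0.01, max_iter = 200L) {
  stopifnot(inherits(params, "leaf_parameters"))
  t_air <- forcing$air_temperature
  check_number(t_air, "air_temperature")
  sw <- if (params$exposure == "sun") {
    forcing$direct_solar + forcing$diffuse_solar
  } else {
    forcing$diffuse_solar
  }
  if (sw < 0) abort_field("solar flux", "must be non-negative")
  if (is.null(ground_temperature)) ground_temperature <- t_air
  eps <- params$emissivity
  t_sky_k <- celsius_to_kelvin(forcing$sky_temperature)
  t_ground_k <- celsius_to_kelvin(ground_temperature)
  r_abs <- params$absorptance * sw +
    eps * SIGMA_SB * (t_sky_k^4 + t_ground_k^4)
  g_bl <- boundary_layer_conductance(forcing$wind, params$dimension)
  g_h <- 2 * g_bl
  g_s <- params$stomatal_conductance
  g_v <- if (g_s > 0) 1 / (1 / g_s + 1 / g_bl) else 0
  e_a <- forcing$relative_humidity / 100 * saturation_vp(t_air)

  latent <- function(t_leaf) {
    if (g_v == 0) return(0)
    LAMBDA_MOLAR * g_v * max(saturation_vp(t_leaf) - e_a, 0) / pressure
  }
  resid <- function(t_leaf) {
    t_k <- celsius_to_kelvin(t_leaf)
    r_abs - 2 * eps * SIGMA_SB * t_k^4 -
      CP_MOLAR * g_h * (t_leaf - t_air) - latent(t_leaf)
  }
  dresid <- function(t_leaf) {
    t_k <- celsius_to_kelvin(t_leaf)
    dl <- if (g_v > 0 && saturation_vp(t_leaf) > e_a) {
      LAMBDA_MOLAR * g_v * saturation_vp_slope(t_leaf) / pressure
    } else {
      0
    }
    -8 * eps * SIGMA_SB * t_k^3 - CP_MOLAR * g_h - dl
  }

  lo <- t_air - 20
  hi <- t_air + 30
  f_lo <- resid(lo)
  f_hi <- resid(hi)
  if (sign(f_lo) == sign(f_hi)) {
    stop(sprintf(
      paste("no sign change in the bracket [%.1f, %.1f] degC:",
            "residuals %.2f and %.2f W m-2"),
      lo, hi, f_lo, f_hi
    ), call. = FALSE)
  }
  t_leaf <- t_air
  f <- resid(t_leaf)
  iter <- 0L
  while (abs(f) > tol && iter < max_iter) {
    step <- -f / dresid(t_leaf)
    cand <- t_leaf + step
    if (!is.finite(cand) || cand <= lo || cand >= hi) {
      cand <- (lo + hi) / 2  # bisection fallback
    }
    f_cand <- resid(cand)
    # maintain the bracket (resid is decreasing in t_leaf)
    if (f_cand > 0) lo <- cand else hi <- cand
    t_leaf <- cand
    f <- f_cand
    iter <- iter + 1L
  }
  if (abs(f) > tol) {
    stop(sprintf("leaf energy budget did not converge (residual %.3g W m-2)",
                 f), call. = FALSE)
  }
  t_k <- celsius_to_kelvin(t_leaf)
  l_out <- 2 * eps * SIGMA_SB * t_k^4
  h <- CP_MOLAR * g_h * (t_leaf - t_air)
  le <- latent(t_leaf)
  list(
    leaf_temperature = t_leaf,
    excess = t_leaf - t_air,
    fluxes = c(r_abs = r_abs, l_out = l_out, sensible = h, latent = le,
               residual = r_abs - l_out - h - le)
  )
}

#' Solve the leaf energy budget over an hourly series
#'
#' Element-wise [solve_leaf_temperature()] over a microclimate series,
#' carrying the component fluxes for audit.
#'
#' @param series A [generate_microclimate()] result (or any data frame with
#'   the same columns).
#' @param params A [leaf_parameters()].
#' @param ground_temperature Optional ground temperature (degC); defaults
#'   to each hour's air temperature.
#' @return A data frame (class `leaf_temperature_series`): the input series
#'   plus `leaf_temperature`, `excess`, `r_abs`, `l_out`, `sensible`,
#'   `latent` and `residual` columns.
#' @export
leaf_series <- function(series, params, ground_temperature = NULL) {
  pressure <- attr(series, "pressure")
  if (is.null(pressure)) pressure <- P_ATM
  sol <- lapply(seq_len(nrow(series)), function(i) {
    tryCatch(
      solve_leaf_temperature(series[i, ], params,
                             ground_temperature = ground_temperature,
                             pressure = pressure),
      error = function(e) {
        stop(sprintf("hour %s: %s", series$hour[i], conditionMessage(e)),
             call. = FALSE)
      }
    )
  })
  out <- series
  out$leaf_temperature <- vapply(sol, `[[`, numeric(1), "leaf_temperature")
  out$excess <- vapply(sol, `[[`, numeric(1), "excess")
  fx <- t(vapply(sol, `[[`, numeric(5), "fluxes"))
  out[c("r_abs", "l_out", "sensible", "latent", "residual")] <-
    as.data.frame(fx)
  class(out) <- c("leaf_temperature_series", class(series))
  out
}

#' Validate predicted leaf temperature excess against observations
#'
#' Compares model-predicted leaf temperature excess with field observations
#' from sun-exposed and shaded leaves using two criteria: (i) the model's
#' mean estimation error must be smaller than the observed sun-minus-shade
#' difference, and (ii) smaller than the organism's thermal safety margin
#' (LT50 minus maximum ambient temperature).
#'
#' @param predicted_excess Predicted excess values (degC) for sun-exposed
#'   leaves.
#' @param observed_excess_sun,observed_excess_shade Observed excess values
#'   (degC).
#' @param lt50 Upper lethal temperature of the focal organism (degC).
#' @param max_ambient Maximum ambient (microhabitat) temperature (degC).
#' @return List with `estimation_error`, `sun_shade_difference`,
#'   `safety_margin`, `criterion_error_lt_sun_shade` and
#'   `criterion_error_lt_margin`.
#' @export
validate_against_observations <- function(predicted_excess,
                                          observed_excess_sun,
                                          observed_excess_shade,
                                          lt50, max_ambient) {
  if (length(predicted_excess) == 0L || length(observed_excess_sun) == 0L ||
      length(observed_excess_shade) == 0L) {
    stop("observation and prediction sets must be non-empty", call. = FALSE)
  }
  err <- abs(mean(predicted_excess) - mean(observed_excess_sun))
  diff_ss <- mean(observed_excess_sun) - mean(observed_excess_shade)
  margin <- safety_margin(lt50, max_ambient)
  list(
    estimation_error = err,
    sun_shade_difference = diff_ss,
    safety_margin = margin,
    criterion_error_lt_sun_shade = err < diff_ss,
    criterion_error_lt_margin = err < margin
  )
}
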