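# Structured run configuration: YAML schema, validation, object building.

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0L) {
    stop(sprintf("config: unknown key(s) under `%s`: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

require_keys <- function(x, required, where) {
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop(sprintf("config: missing key(s) under `%s`: %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read and validate a structured run configuration
#'
#' Parses a YAML run configuration describing the site (with monthly
#' normals), warming scenarios, leaf parameters, synthetic-data designs,
#' analysis options and the master seed, and builds the corresponding
#' package objects. Unknown keys anywhere in the file are rejected.
#'
#' The shipped example configuration for a Rocky Mountain aspen site is at
#' `system.file("extdata", "mpg_north.yaml", package = "parasitherm")`.
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config`: list with `seed`, `site`
#'   ([site_spec()]), `scenarios` (list of [scenario_spec()]), `leaf_sun`,
#'   `leaf_shade` ([leaf_parameters()]), `designs` (heat-shock host and
#'   parasitoid, gradient, emergence), `analysis` options and `months`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, c("seed", "site", "scenarios", "leaf", "designs",
                    "analysis", "months"), "<top level>")
  require_keys(cfg, c("seed", "site", "scenarios", "leaf", "designs"),
               "<top level>")
  seed <- check_count(cfg$seed, "seed", min = 0L)

  s <- cfg$site
  check_keys(s, c("latitude", "longitude", "elevation", "reference_height",
                  "transmittance", "normals"), "site")
  require_keys(s, c("latitude", "normals"), "site")
  normals <- do.call(rbind, lapply(s$normals, function(n) {
    check_keys(n, c("month", "t_min", "t_max", "wind_mean", "rh_mean",
                    "cloud_fraction"), "site$normals")
    require_keys(n, c("month", "t_min", "t_max", "wind_mean", "rh_mean",
                      "cloud_fraction"), "site$normals")
    as.data.frame(n)
  }))
  site <- site_spec(
    latitude = s$latitude,
    longitude = s$longitude %||% 0,
    elevation = s$elevation %||% 0,
    reference_height = s$reference_height %||% 1.2,
    normals = normals,
    transmittance = s$transmittance %||% 0.70
  )

  if (length(cfg$scenarios) == 0L) {
    stop("config: at least one scenario is required", call. = FALSE)
  }
  scenarios <- lapply(cfg$scenarios, function(sc) {
    check_keys(sc, c("name", "delta"), "scenarios")
    require_keys(sc, c("name", "delta"), "scenarios")
    scenario_spec(sc$name, unlist(sc$delta))
  })

  lf <- cfg$leaf
  check_keys(lf, c("absorptance", "emissivity", "dimension",
                   "stomatal_conductance"), "leaf")
  leaf_args <- list(
    absorptance = lf$absorptance %||% 0.5,
    emissivity = lf$emissivity %||% 0.97,
    dimension = lf$dimension %||% 0.05,
    stomatal_conductance = lf$stomatal_conductance %||% 0.2
  )
  leaf_sun <- do.call(leaf_parameters, c(leaf_args, exposure = "sun"))
  leaf_shade <- do.call(leaf_parameters, c(leaf_args, exposure = "shade"))

  ds <- cfg$designs
  check_keys(ds, c("heat_shock_host", "heat_shock_parasitoid", "gradient",
                   "emergence"), "designs")
  require_keys(ds, c("heat_shock_host", "heat_shock_parasitoid",
                     "gradient", "emergence"), "designs")
  hs_design <- function(d, species, seed_offset, where) {
    check_keys(d, c("shock_temperatures", "n_per_temperature", "true_lt50",
                    "true_slope"), where)
    heat_shock_design(
      shock_temperatures = unlist(d$shock_temperatures),
      n_per_temperature = d$n_per_temperature %||% 7L,
      true_lt50 = d$true_lt50,
      true_slope = d$true_slope,
      species = species,
      seed = seed + seed_offset
    )
  }
  g <- ds$gradient
  check_keys(g, c("n_individuals", "tpref_mean", "tpref_sd",
                  "rearing_temperatures", "bar_cold_end", "bar_hot_end",
                  "n_positions"), "designs$gradient")
  e <- ds$emergence
  check_keys(e, c("rearing_temperatures", "n_leaves_per_temperature",
                  "host", "parasitoid", "emergence_probability"),
             "designs$emergence")
  designs <- list(
    heat_shock_host = hs_design(ds$heat_shock_host, "host", 1L,
                                "designs$heat_shock_host"),
    heat_shock_parasitoid = hs_design(ds$heat_shock_parasitoid,
                                      "parasitoid", 2L,
                                      "designs$heat_shock_parasitoid"),
    gradient = gradient_design(
      n_individuals = g$n_individuals %||% 135L,
      tpref_mean = g$tpref_mean %||% 20.1,
      tpref_sd = g$tpref_sd %||% 4.5,
      rearing_temperatures = unlist(g$rearing_temperatures %||%
                                      c(15, 20, 25, 30, 35)),
      bar_cold_end = g$bar_cold_end %||% 12.5,
      bar_hot_end = g$bar_hot_end %||% 44.5,
      n_positions = g$n_positions %||% 6L,
      seed = seed + 3L
    ),
    emergence = emergence_design(
      rearing_temperatures = unlist(e$rearing_temperatures %||%
                                      c(15, 20, 25, 30, 35)),
      n_leaves_per_temperature = e$n_leaves_per_temperature %||% 150L,
      host = e$host %||% list(dd = 250, t0 = 4, noise_sd = 3),
      parasitoid = e$parasitoid %||% list(dd = 165, t0 = 9.5, noise_sd = 3),
      emergence_probability = unlist(e$emergence_probability %||%
                                       c(host = 0.14, parasitoid = 0.36)),
      seed = seed + 4L
    )
  )

  an <- cfg$analysis %||% list()
  check_keys(an, c("levene_center", "link", "interpolate_positions"),
             "analysis")
  analysis <- list(
    levene_center = an$levene_center %||% "median",
    link = an$link %||% "logit",
    interpolate_positions = isTRUE(an$interpolate_positions)
  )
  if (!analysis$levene_center %in% c("median", "mean")) {
    stop("config: analysis$levene_center must be \"median\" or \"mean\"",
         call. = FALSE)
  }
  if (!analysis$link %in% c("logit", "probit")) {
    stop("config: analysis$link must be \"logit\" or \"probit\"",
         call. = FALSE)
  }

  months <- as.integer(unlist(cfg$months %||% 5:7))

  structure(
    list(seed = seed, site = site, scenarios = scenarios,
         leaf_sun = leaf_sun, leaf_shade = leaf_shade,
         designs = designs, analysis = analysis, months = months),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
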