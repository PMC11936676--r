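# Internal helpers: argument validation and shared physical formulae.

# Stefan-Boltzmann constant, W m-2 K-4
SIGMA_SB <- 5.670374e-8
# molar heat capacity of air, J mol-1 K-1
CP_MOLAR <- 29.3
# molar latent heat of vaporisation of water near 20 degC, J mol-1
LAMBDA_MOLAR <- 44000
# sea-level atmospheric pressure, Pa
P_ATM <- 101325

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_field(field, "must be a single non-missing number")
  }
  if (finite && !is.finite(x)) abort_field(field, "must be finite")
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  check_number(x, field)
  if (x < min || x != as.integer(x)) {
    abort_field(field, sprintf("must be an integer >= %d", min))
  }
  invisible(as.integer(x))
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort_field(field, "must be TRUE or FALSE")
  }
  invisible(x)
}

# Tetens saturation vapour pressure over water, Pa, T in degC
saturation_vp <- function(temp_c) {
  610.78 * exp(17.27 * temp_c / (temp_c + 237.3))
}

# slope of saturation vapour pressure, Pa per K
saturation_vp_slope <- function(temp_c) {
  es <- saturation_vp(temp_c)
  es * 17.27 * 237.3 / (temp_c + 237.3)^2
}

celsius_to_kelvin <- function(temp_c) temp_c + 273.15
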