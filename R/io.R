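# CSV dialects: column names, types and per-row invariants for the tabular
# formats the package reads and writes.

dialect_schema <- function(dialect) {
  switch(dialect,
    heat_shock = list(
      columns = c(individual_id = "character", species = "character",
                  shock_temperature = "numeric", survived = "numeric"),
      optional = character(0),
      check = function(row) {
        if (!row$survived %in% c(0, 1)) return("`survived` must be 0 or 1")
        if (!is.finite(row$shock_temperature)) {
          return("`shock_temperature` must be finite")
        }
        NULL
      }
    ),
    gradient = list(
      columns = c(individual_id = "character",
                  rearing_temperature = "numeric",
                  position_control = "numeric",
                  position_gradient = "numeric"),
      optional = c(dry_mass = "numeric"),
      check = function(row) {
        if (row$position_control < 1 || row$position_gradient < 1) {
          return("positions must be >= 1")
        }
        NULL
      }
    ),
    emergence = list(
      columns = c(insect_type = "character",
                  rearing_temperature = "numeric",
                  days_to_emergence = "numeric"),
      optional = character(0),
      check = function(row) {
        if (!row$insect_type %in% c("host", "parasitoid")) {
          return("`insect_type` must be \"host\" or \"parasitoid\"")
        }
        if (row$days_to_emergence <= 0) {
          return("`days_to_emergence` must be positive")
        }
        NULL
      }
    ),
    microclimate = list(
      columns = c(hour = "numeric", air_temperature = "numeric",
                  direct_solar = "numeric", diffuse_solar = "numeric",
                  wind = "numeric", relative_humidity = "numeric",
                  sky_temperature = "numeric", zenith_angle = "numeric"),
      optional = character(0),
      check = function(row) {
        if (row$direct_solar < 0 || row$diffuse_solar < 0) {
          return("solar fluxes must be non-negative")
        }
        if (row$relative_humidity <= 0 || row$relative_humidity > 100) {
          return("`relative_humidity` must be in (0, 100]")
        }
        NULL
      }
    ),
    stop("unknown dialect: ", dialect, call. = FALSE)
  )
}

#' Read a typed CSV table in one of the package dialects
#'
#' Reads and validates one of the package's tabular formats. The header
#' must contain exactly the dialect's columns (plus its optional columns);
#' cells are type-checked and per-row invariants enforced, with errors
#' reporting the offending row and column.
#'
#' @param path Path to a CSV file (RFC 4180, UTF-8, `.` decimal).
#' @param dialect One of `"heat_shock"`, `"gradient"`, `"emergence"`,
#'   `"microclimate"`.
#' @return A validated data frame (possibly with zero rows).
#' @export
read_table <- function(path, dialect = c("heat_shock", "gradient",
                                         "emergence", "microclimate")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  schema <- dialect_schema(dialect)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- names(schema$columns)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  allowed <- c(required, names(schema$optional))
  extra <- setdiff(names(df), allowed)
  if (length(extra) > 0L) {
    stop(sprintf("%s: unexpected column(s): %s", path,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  types <- c(schema$columns, schema$optional)[names(df)]
  for (col in names(df)) {
    if (types[[col]] == "numeric") {
      val <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(val) & !is.na(df[[col]]) & df[[col]] != "")
      if (length(bad) > 0L) {
        stop(sprintf("%s: row %d, column `%s`: cannot parse \"%s\" as number",
                     path, bad[1], col, df[[col]][bad[1]]), call. = FALSE)
      }
      na_rows <- which(is.na(val))
      if (length(na_rows) > 0L && !col %in% names(schema$optional)) {
        stop(sprintf("%s: row %d, column `%s`: missing value",
                     path, na_rows[1], col), call. = FALSE)
      }
      df[[col]] <- val
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  for (i in seq_len(nrow(df))) {
    msg <- schema$check(df[i, , drop = FALSE])
    if (!is.null(msg)) {
      stop(sprintf("%s: row %d: %s", path, i, msg), call. = FALSE)
    }
  }
  df[required] <- df[required]
  df
}

#' Write a table in the package CSV convention
#'
#' Writes a data frame as RFC 4180 CSV with every numeric formatted to six
#' significant digits, so output files are stable across platforms and
#' round-trip byte-identically through [read_table()] / `write_table()`.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  out <- x
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- formatC(signif(out[[col]], 6), format = "g",
                            digits = 6)
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
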