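#' Fit the emergence-timing linear model
#'
#' Ordinary least squares of days to emergence on rearing temperature
#' (continuous), insect type (0/1 indicator, host as reference) and their
#' interaction, solved by QR (orthogonal) decomposition via [stats::lm()].
#' Temperature is continuous because a single model degree of freedom is
#' the conventional treatment when the temperature levels are ordered doses
#' rather than unstructured groups; a categorical version is available with
#' `categorical_temperature = TRUE`.
#'
#' @param records Data frame with columns `insect_type` (`"host"` /
#'   `"parasitoid"`), `rearing_temperature` (degC) and `days_to_emergence`.
#' @param categorical_temperature Treat rearing temperature as a factor.
#' @return An object of class `emergence_fit`: list with `lm` (the
#'   underlying fit), `coefficients`, `rss`, `df_residual`, `n`.
#' @export
fit_emergence_lm <- function(records, categorical_temperature = FALSE) {
  req <- c("insect_type", "rearing_temperature", "days_to_emergence")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    abort_field("records", paste("must have columns",
                                 paste0("`", req, "`", collapse = ", ")))
  }
  if (any(records$days_to_emergence <= 0)) {
    abort_field("days_to_emergence", "must be positive")
  }
  types <- unique(records$insect_type)
  if (length(types) < 2L) {
    stop("both insect types must be present; the `insect_type` term is ",
         "aliased with the intercept otherwise", call. = FALSE)
  }
  if (length(unique(records$rearing_temperature)) < 2L) {
    stop("need at least 2 rearing temperatures; the `rearing_temperature` ",
         "term is aliased with the intercept otherwise", call. = FALSE)
  }
  d <- data.frame(
    days = records$days_to_emergence,
    temperature = if (categorical_temperature) {
      factor(records$rearing_temperature)
    } else {
      records$rearing_temperature
    },
    type = factor(records$insect_type, levels = sort(unique(records$insect_type)))
  )
  fit <- lm(days ~ temperature + type + temperature:type, data = d)
  if (anyNA(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      lm = fit,
      coefficients = coef(fit),
      rss = sum(fit$residuals^2),
      df_residual = fit$df.residual,
      n = nrow(d)
    ),
    class = "emergence_fit"
  )
}

#' Assemble an ANOVA table from sums of squares
#'
#' Builds the standard ANOVA bookkeeping (mean squares, F ratios and
#' p-values against the residual mean square) from term degrees of freedom
#' and sums of squares. Used internally by [anova_sequential()]; also handy
#' for recomputing F statistics from a published sequential decomposition.
#'
#' @param terms Data frame with columns `term`, `df`, `sum_sq`.
#' @param residual_df,residual_ss Residual degrees of freedom and sum of
#'   squares.
#' @return An object of class `anova_table`: a data frame with columns
#'   `term`, `df`, `sum_sq`, `mean_sq`, `F`, `p`, ending in the residual
#'   row.
#' @examples
#' anova_table(
#'   data.frame(term = c("temperature", "insect type", "temperature:type"),
#'              df = 1, sum_sq = c(24446.8, 932.7, 324.2)),
#'   residual_df = 367, residual_ss = 7781.8
#' )
#' @export
anova_table <- function(terms, residual_df, residual_ss) {
  if (!is.data.frame(terms) ||
      !all(c("term", "df", "sum_sq") %in% names(terms))) {
    abort_field("terms", "must have columns `term`, `df`, `sum_sq`")
  }
  residual_df <- check_count(residual_df, "residual_df")
  check_number(residual_ss, "residual_ss")
  if (residual_ss < 0) abort_field("residual_ss", "must be non-negative")
  ms_res <- residual_ss / residual_df
  mean_sq <- terms$sum_sq / terms$df
  f <- mean_sq / ms_res
  p <- pf(f, terms$df, residual_df, lower.tail = FALSE)
  out <- rbind(
    data.frame(term = as.character(terms$term), df = terms$df,
               sum_sq = terms$sum_sq, mean_sq = mean_sq, F = f, p = p,
               stringsAsFactors = FALSE),
    data.frame(term = "residuals", df = residual_df, sum_sq = residual_ss,
               mean_sq = ms_res, F = NA_real_, p = NA_real_,
               stringsAsFactors = FALSE)
  )
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Sequential (Type-I) ANOVA of an emergence-timing fit
#'
#' Sequential sums of squares in the entry order temperature, type,
#' temperature:type; each F is the term mean square over the residual mean
#' square. The term and residual sums of squares add up to the total
#' corrected sum of squares.
#'
#' @param fit An [fit_emergence_lm()] result.
#' @return An [anova_table()].
#' @export
anova_sequential <- function(fit) {
  stopifnot(inherits(fit, "emergence_fit"))
  if (fit$df_residual < 1L) {
    stop("zero residual degrees of freedom: F ratios undefined",
         call. = FALSE)
  }
  tab <- anova(fit$lm)
  k <- nrow(tab)
  anova_table(
    data.frame(
      term = rownames(tab)[-k],
      df = tab$Df[-k],
      sum_sq = tab$`Sum Sq`[-k]
    ),
    residual_df = tab$Df[k],
    residual_ss = tab$`Sum Sq`[k]
  )
}

#' Gaussian maximum-likelihood AIC of a linear fit
#'
#' `n * log(2 * pi * RSS / n) + n + 2 * (k + 1)` where `k` is the number of
#' regression coefficients (the `+1` counts the error variance). Matches
#' [stats::AIC()] on `lm` fits; provided so nested fixed-effects emergence
#' models can be ranked directly.
#'
#' @param fit An `emergence_fit`, or any list with elements `rss`, `n` and
#'   `coefficients`.
#' @return AIC (dimensionless).
#' @export
lm_aic <- function(fit) {
  rss <- fit$rss
  n <- fit$n
  k <- length(fit$coefficients)
  if (is.null(rss) || is.null(n) || k == 0L) {
    abort_field("fit", "must carry `rss`, `n` and `coefficients`")
  }
  if (rss <= 0) {
    stop("residual sum of squares is zero: the Gaussian likelihood is ",
         "degenerate and AIC undefined", call. = FALSE)
  }
  n * log(2 * pi * rss / n) + n + 2 * (k + 1)
}

#' Append development rate (1/days) to emergence records
#'
#' @param records Data frame with a positive `days_to_emergence` column.
#' @return The same data frame with a `rate` column (per day).
#' @export
development_rate <- function(records) {
  if (nrow(records) == 0L) {
    records$rate <- numeric(0)
    return(records)
  }
  if (any(records$days_to_emergence <= 0)) {
    abort_field("days_to_emergence", "must be positive")
  }
  records$rate <- 1 / records$days_to_emergence
  records
}

#' Emergence proportions from leaf counts
#'
#' Per-type emergence proportions given the number of leaves reared and the
#' number of emergences of each type.
#'
#' @param n_leaves Total leaves reared.
#' @param counts Named integer vector of emergence counts by type; any
#'   shortfall from `n_leaves` is reported as `none`.
#' @return Data frame with columns `outcome`, `count`, `proportion`.
#' @examples
#' emergence_proportions(750, c(host = 107, parasitoid = 270))
#' @export
emergence_proportions <- function(n_leaves, counts) {
  n_leaves <- check_count(n_leaves, "n_leaves")
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort_field("counts", "must be a named vector")
  }
  if (any(counts < 0) || sum(counts) > n_leaves) {
    abort_field("counts", "must be non-negative and sum to at most n_leaves")
  }
  all_counts <- c(counts, none = n_leaves - sum(counts))
  data.frame(
    outcome = names(all_counts),
    count = as.numeric(all_counts),
    proportion = as.numeric(all_counts) / n_leaves,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
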