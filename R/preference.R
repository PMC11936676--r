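#' Geometry of a linear thermal-gradient bar
#'
#' Describes the mapping between marked positions along a gradient bar and
#' temperature: the two end temperatures, the number of marks, and which
#' end carries the first position label. With `cold_end_position = "last"`
#' (the default) higher position labels are closer to the cold end.
#'
#' @param cold_end,hot_end Temperatures at the cold and hot ends (degC).
#' @param n_positions Number of equally spaced marks.
#' @param cold_end_position `"last"` or `"first"`: which mark label sits at
#'   the cold end.
#' @return An object of class `gradient_spec`.
#' @export
gradient_spec <- function(cold_end = 12.5, hot_end = 44.5,
                          n_positions = 6L,
                          cold_end_position = c("last", "first")) {
  check_number(cold_end, "cold_end")
  check_number(hot_end, "hot_end")
  if (cold_end >= hot_end) abort_field("cold_end", "must be below hot_end")
  n_positions <- check_count(n_positions, "n_positions", min = 2L)
  cold_end_position <- match.arg(cold_end_position)
  structure(
    list(
      cold_end = cold_end, hot_end = hot_end,
      n_positions = n_positions, cold_end_position = cold_end_position
    ),
    class = "gradient_spec"
  )
}

#' Convert a bar position to temperature
#'
#' Linear interpolation between the end temperatures across the marks. The
#' map is affine in the position label; orientation is taken from the
#' spec's `cold_end_position`.
#'
#' @param position Mark label(s), possibly fractional, within
#'   `[1, n_positions]`.
#' @param spec A [gradient_spec()].
#' @return Temperature(s) in degC.
#' @examples
#' sp <- gradient_spec(12.5, 44.5, 6)
#' position_to_temperature(5, sp)  # one mark from the cold end
#' @export
position_to_temperature <- function(position, spec) {
  stopifnot(inherits(spec, "gradient_spec"))
  if (any(!is.finite(position)) ||
      any(position < 1 - 1e-9) || any(position > spec$n_positions + 1e-9)) {
    abort_field("position", sprintf("must lie within [1, %d]",
                                    spec$n_positions))
  }
  frac <- (position - 1) / (spec$n_positions - 1)
  if (spec$cold_end_position == "first") {
    spec$cold_end + frac * (spec$hot_end - spec$cold_end)
  } else {
    spec$hot_end + frac * (spec$cold_end - spec$hot_end)
  }
}

# inverse of position_to_temperature (continuous position)
temperature_to_position <- function(temperature, spec) {
  stopifnot(inherits(spec, "gradient_spec"))
  if (spec$cold_end_position == "first") {
    frac <- (temperature - spec$cold_end) / (spec$hot_end - spec$cold_end)
  } else {
    frac <- (temperature - spec$hot_end) / (spec$cold_end - spec$hot_end)
  }
  1 + frac * (spec$n_positions - 1)
}

#' Brown-Forsythe / Levene test of equality of variances for two groups
#'
#' One-way ANOVA on absolute deviations from each group's centre. The
#' default centre is the group median (the Brown-Forsythe form, robust to
#' non-normality); the classical mean-centred Levene statistic is available
#' via `center = "mean"`.
#'
#' @param group_a,group_b Numeric vectors (e.g. settling positions in
#'   control and gradient runs), each with at least two values.
#' @param center `"median"` (default) or `"mean"`.
#' @return List with `F`, `df` (numerator, denominator) and `p`.
#' @export
levene_test <- function(group_a, group_b, center = c("median", "mean")) {
  center <- match.arg(center)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  cfun <- if (center == "median") median else mean
  dev_a <- abs(group_a - cfun(group_a))
  dev_b <- abs(group_b - cfun(group_b))
  if (all(c(dev_a, dev_b) == 0)) {
    stop("all within-group deviations are zero: F is undefined",
         call. = FALSE)
  }
  z <- c(dev_a, dev_b)
  g <- factor(rep(c("a", "b"), c(length(dev_a), length(dev_b))))
  tab <- anova(lm(z ~ g))
  list(
    F = tab[["F value"]][1],
    df = c(tab$Df[1], tab$Df[2]),
    p = tab[["Pr(>F)"]][1]
  )
}

#' Paired test of position shift between control and gradient runs
#'
#' One-sample t test of the per-individual differences
#' `position_gradient - position_control` against zero. A significant
#' positive mean (with cold-end-last labelling) means individuals moved
#' toward the cold end when the gradient was on.
#'
#' @param trials Data frame with columns `position_control` and
#'   `position_gradient`, one row per individual.
#' @return List with `mean_diff`, `t`, `df` and `p`.
#' @export
paired_position_test <- function(trials) {
  if (!is.data.frame(trials) ||
      !all(c("position_control", "position_gradient") %in% names(trials))) {
    abort_field("trials",
                "must have columns `position_control` and `position_gradient`")
  }
  d <- trials$position_gradient - trials$position_control
  d <- d[is.finite(d)]
  if (length(d) < 2L) {
    stop("need at least 2 paired observations", call. = FALSE)
  }
  if (var(d) == 0) {
    stop("differences have zero variance: t is undefined", call. = FALSE)
  }
  ht <- t.test(d, mu = 0)
  list(
    mean_diff = unname(ht$estimate),
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value
  )
}

#' Confidence interval for a mean from its sample moments
#'
#' Student-t interval `mean +/- qt(0.975, n - 1) * sd / sqrt(n)`. Useful to
#' reconstruct a preferred-temperature confidence interval from published
#' summary moments.
#'
#' @param mean,sd Sample mean and standard deviation.
#' @param n Sample size (>= 2).
#' @param level Confidence level, default 0.95.
#' @return Named vector `c(lower, upper)`.
#' @export
tpref_ci <- function(mean, sd, n, level = 0.95) {
  check_number(mean, "mean")
  check_number(sd, "sd")
  n <- check_count(n, "n", min = 2L)
  if (sd < 0) abort_field("sd", "must be non-negative")
  half <- qt(1 - (1 - level) / 2, n - 1) * sd / sqrt(n)
  c(lower = mean - half, upper = mean + half)
}

#' Summarise a sample of preferred temperatures
#'
#' Sample mean, standard deviation and Student-t 95% confidence interval of
#' a vector of preferred temperatures.
#'
#' @param temperatures Numeric vector of temperatures (degC), `n >= 2`.
#' @param level Confidence level.
#' @return List with `n`, `mean`, `sd` and `ci95 = c(lower, upper)`.
#' @export
summarize_tpref <- function(temperatures, level = 0.95) {
  temperatures <- temperatures[is.finite(temperatures)]
  n <- length(temperatures)
  if (n < 2L) stop("need at least 2 temperatures", call. = FALSE)
  m <- mean(temperatures)
  s <- sd(temperatures)
  list(n = n, mean = m, sd = s, ci95 = tpref_ci(m, s, n, level))
}

#' Regression ANOVA of preferred temperature on rearing temperature
#'
#' Tests whether thermal preference depends on rearing (developmental)
#' temperature. Rearing temperature enters as a continuous covariate by
#' default (single numerator degree of freedom, F on `(1, n - 2)` df); a
#' categorical factor version is available with `categorical = TRUE`.
#'
#' @param temperatures Preferred temperatures (degC).
#' @param rearing_temperatures Rearing temperatures (degC), same length.
#' @param categorical Treat rearing temperature as a factor.
#' @return List with `F`, `df`, `p` and `perfect_fit` (`TRUE` when the
#'   residual sum of squares is numerically zero, in which case `F` is
#'   infinite).
#' @export
anova_tpref_by_rearing <- function(temperatures, rearing_temperatures,
                                   categorical = FALSE) {
  if (length(temperatures) != length(rearing_temperatures)) {
    abort_field("rearing_temperatures", "must match `temperatures` in length")
  }
  if (length(unique(rearing_temperatures)) < 2L) {
    stop("rearing temperature is constant: no variance to analyse",
         call. = FALSE)
  }
  x <- if (categorical) factor(rearing_temperatures) else rearing_temperatures
  fit <- lm(temperatures ~ x)
  # perfect fits are detected and flagged below; silence anova's own notice
  tab <- suppressWarnings(anova(fit))
  rss <- tab$`Sum Sq`[2]
  tss <- sum(tab$`Sum Sq`)
  perfect <- rss <= 1e-10 * max(tss, 1)
  list(
    F = if (perfect) Inf else tab[["F value"]][1],
    df = c(tab$Df[1], tab$Df[2]),
    p = if (perfect) 0 else tab[["Pr(>F)"]][1],
    perfect_fit = perfect
  )
}

#' Full preference analysis of paired gradient trials
#'
#' Runs the complete preference analysis on paired control/gradient trials:
#' variance-equality (Brown-Forsythe) test of positions, paired position
#' test, preferred-temperature summary at the chosen marks, and the
#' regression ANOVA of preference on rearing temperature.
#'
#' @param trials Data frame as returned by [simulate_gradient_trials()] or
#'   [read_table()] with the `gradient` dialect.
#' @param spec A [gradient_spec()] describing the bar.
#' @param center Centre for the variance test, `"median"` or `"mean"`.
#' @param interpolate Use continuous (fractional) positions when mapping to
#'   temperature; by default positions are used as recorded (mark labels).
#' @return An object of class `preference_summary`: a list with `n`,
#'   `tpref` (mean/sd/ci95), `levene`, `paired` and `rearing_anova`.
#' @export
preference_summary <- function(trials, spec = gradient_spec(),
                               center = c("median", "mean"),
                               interpolate = FALSE) {
  center <- match.arg(center)
  pos <- trials$position_gradient
  if (!interpolate) pos <- round(pos)
  temps <- position_to_temperature(pos, spec)
  lev <- levene_test(trials$position_control, trials$position_gradient,
                     center = center)
  pair <- paired_position_test(trials)
  tp <- summarize_tpref(temps)
  an <- anova_tpref_by_rearing(temps, trials$rearing_temperature)
  structure(
    list(n = tp$n, tpref = tp, levene = lev, paired = pair,
         rearing_anova = an),
    class = "preference_summary"
  )
}

#' @export
print.preference_summary <- function(x, ...) {
  cat("Thermal preference summary (n =", x$n, ")\n")
  cat(sprintf("  T_pref: mean %.2f degC, sd %.2f, 95%% CI (%.2f, %.2f)\n",
              x$tpref$mean, x$tpref$sd, x$tpref$ci95[["lower"]],
              x$tpref$ci95[["upper"]]))
  cat(sprintf("  Variance test (control vs gradient): F(%d, %d) = %.3f, p = %.3g\n",
              x$levene$df[1], x$levene$df[2], x$levene$F, x$levene$p))
  cat(sprintf("  Paired position shift: mean %.3f, t(%d) = %.3f, p = %.3g\n",
              x$paired$mean_diff, x$paired$df, x$paired$t, x$paired$p))
  cat(sprintf("  Preference ~ rearing: F(%d, %d) = %.3f, p = %.3g\n",
              x$rearing_anova$df[1], x$rearing_anova$df[2],
              x$rearing_anova$F, x$rearing_anova$p))
  invisible(x)
}
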