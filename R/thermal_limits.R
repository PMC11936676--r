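#' Fit a binomial-logistic dose-response of survival on shock temperature
#'
#' Maximum-likelihood logistic regression of individual survival (0/1) on
#' acute heat-shock temperature, fitted by iteratively reweighted least
#' squares with step-halving so the deviance never increases between
#' iterations. The median lethal temperature LT50 is `-b0 / b` with a
#' delta-method standard error from the observed-information covariance.
#'
#' Grouped binomial data (survivors out of exposed per temperature) should
#' be expanded to one row per individual before fitting; the maximum
#' likelihood estimate is identical.
#'
#' @param records Data frame with columns `shock_temperature` (degC) and
#'   `survived` (0/1), e.g. from [simulate_heat_shock()] or
#'   [read_table()] with the `heat_shock` dialect.
#' @param link Link function; `"logit"` (default) or `"probit"`.
#' @param tol Convergence tolerance on the relative deviance change.
#' @param max_iter Iteration cap.
#' @return An object of class `dose_response_fit` with elements
#'   `coefficients` (`b0`, `b`), `vcov`, `lt50`, `lt50_se`, `n`, `deviance`,
#'   `deviance_trace`, `converged`, `iterations`, `link` and
#'   `mortality_table` (observed death fraction per shock temperature).
#' @details Complete separation (the temperature ranges of survivors and
#'   non-survivors do not overlap) makes the maximum-likelihood slope
#'   infinite; it is detected up front and reported as an explicit error
#'   rather than returned as a huge unstable estimate.
#' @examples
#' rec <- simulate_heat_shock(heat_shock_design(n_per_temperature = 25, seed = 7))
#' fit <- fit_logistic_survival(rec)
#' lt50(fit)
#' @export
fit_logistic_survival <- function(records, link = c("logit", "probit"),
                                  tol = 1e-10, max_iter = 100L) {
  link <- match.arg(link)
  if (!is.data.frame(records) ||
      !all(c("shock_temperature", "survived") %in% names(records))) {
    abort_field("records",
                "must have columns `shock_temperature` and `survived`")
  }
  x <- as.numeric(records$shock_temperature)
  y <- as.numeric(records$survived)
  if (anyNA(x) || any(!is.finite(x))) {
    abort_field("shock_temperature", "must be finite")
  }
  if (!all(y %in% c(0, 1))) abort_field("survived", "must be 0 or 1")
  if (length(unique(x)) < 2L) {
    stop("need at least 2 distinct shock temperatures", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("need both survivors and non-survivors to fit a dose-response",
         call. = FALSE)
  }
  if (max(x[y == 1]) < min(x[y == 0]) || max(x[y == 0]) < min(x[y == 1])) {
    stop(paste(
      "complete separation: survivor and non-survivor temperature ranges",
      "do not overlap, so the maximum-likelihood slope is infinite"
    ), call. = FALSE)
  }

  linkfun <- switch(link,
    logit = list(inv = plogis, d = function(eta) {
      p <- plogis(eta)
      p * (1 - p)
    }),
    probit = list(inv = pnorm, d = dnorm)
  )
  dev_fun <- function(p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -2 * sum(y * log(p) + (1 - y) * log(1 - p))
  }

  X <- unname(cbind(1, x))
  beta <- c(0, 0)
  dev <- dev_fun(linkfun$inv(drop(X %*% beta)))
  trace <- dev
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- linkfun$inv(eta)
    mu_eta <- pmax(linkfun$d(eta), 1e-12)
    varmu <- pmax(mu * (1 - mu), 1e-12)
    w <- mu_eta^2 / varmu
    z <- eta + (y - mu) / mu_eta
    XtW <- t(X * w)
    step_beta <- tryCatch(solve(XtW %*% X, XtW %*% z),
                          error = function(e) NULL)
    if (is.null(step_beta)) {
      stop("singular weighted design; fit is unstable", call. = FALSE)
    }
    # step-halve until the deviance does not increase
    new_beta <- drop(step_beta)
    frac <- 1
    repeat {
      cand <- beta + frac * (new_beta - beta)
      new_dev <- dev_fun(linkfun$inv(drop(X %*% cand)))
      if (new_dev <= dev + 1e-12 || frac < 1e-8) break
      frac <- frac / 2
    }
    beta <- cand
    trace <- c(trace, new_dev)
    if (abs(new_dev - dev) / (abs(dev) + 0.1) < tol) {
      dev <- new_dev
      converged <- TRUE
      break
    }
    dev <- new_dev
  }

  eta <- drop(X %*% beta)
  mu <- linkfun$inv(eta)
  mu_eta <- pmax(linkfun$d(eta), 1e-12)
  varmu <- pmax(mu * (1 - mu), 1e-12)
  w <- mu_eta^2 / varmu
  info <- t(X * w) %*% X
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 2, 2))
  dimnames(vc) <- list(c("b0", "b"), c("b0", "b"))

  b0 <- beta[1]
  b <- beta[2]
  if (abs(b) > 1e-8) {
    est <- -b0 / b
    grad <- c(-1 / b, b0 / b^2)
    se <- sqrt(pmax(drop(t(grad) %*% vc %*% grad), 0))
  } else {
    est <- NA_real_
    se <- NA_real_
  }
  mt <- tapply(1 - y, x, mean)
  structure(
    list(
      coefficients = c(b0 = b0, b = b),
      vcov = vc,
      lt50 = est,
      lt50_se = se,
      n = length(y),
      deviance = dev,
      deviance_trace = trace,
      converged = converged,
      iterations = iter,
      link = link,
      mortality_table = data.frame(
        shock_temperature = as.numeric(names(mt)),
        death_fraction = as.numeric(mt)
      )
    ),
    class = "dose_response_fit"
  )
}

#' Construct a dose-response fit from known parameters
#'
#' Builds a `dose_response_fit` object directly from a slope/intercept (or
#' from an LT50 and its standard error), for comparing published estimates
#' with [compare_lt50()] or feeding known physiology into
#' [scenario_report()] without refitting.
#'
#' @param lt50 Median lethal temperature (degC). If missing, computed as
#'   `-b0 / b`.
#' @param lt50_se Standard error of `lt50` (degC); if a covariance matrix
#'   `vcov` is supplied instead, the delta method is applied.
#' @param b0,b Intercept and slope on the logit scale. If only `lt50` and a
#'   slope are given, `b0 = -b * lt50`.
#' @param vcov Optional 2x2 covariance matrix of `(b0, b)`.
#' @param n Number of observations behind the estimate, if known.
#' @return A `dose_response_fit` with `converged = TRUE`.
#' @examples
#' host <- dose_response_fit(lt50 = 42.1, b = -0.86, lt50_se = 0.6)
#' para <- dose_response_fit(lt50 = 37.4, b = -0.25, lt50_se = 0.9)
#' compare_lt50(host, para)
#' @export
dose_response_fit <- function(lt50 = NULL, lt50_se = NULL, b0 = NULL,
                              b = NULL, vcov = NULL, n = NA_integer_) {
  if (is.null(b)) abort_field("b", "slope is required")
  check_number(b, "b")
  if (is.null(b0)) {
    if (is.null(lt50)) abort_field("lt50", "either `lt50` or `b0` is required")
    b0 <- -b * lt50
  }
  check_number(b0, "b0")
  if (is.null(lt50)) {
    if (abs(b) < 1e-8) abort_field("b", "slope too close to zero for an LT50")
    lt50 <- -b0 / b
  }
  if (is.null(vcov)) {
    vcov <- matrix(0, 2, 2, dimnames = list(c("b0", "b"), c("b0", "b")))
  }
  if (!is.matrix(vcov) || !all(dim(vcov) == 2) ||
      !isTRUE(all.equal(vcov, t(vcov), tolerance = 1e-8))) {
    abort_field("vcov", "must be a symmetric 2x2 matrix")
  }
  if (is.null(lt50_se)) {
    grad <- c(-1 / b, b0 / b^2)
    lt50_se <- sqrt(pmax(drop(t(grad) %*% vcov %*% grad), 0))
  }
  structure(
    list(
      coefficients = c(b0 = b0, b = b),
      vcov = vcov,
      lt50 = lt50,
      lt50_se = lt50_se,
      n = n,
      deviance = NA_real_,
      deviance_trace = numeric(0),
      converged = TRUE,
      iterations = 0L,
      link = "logit",
      mortality_table = NULL
    ),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Logistic dose-response fit (", x$link, " link)\n", sep = "")
  cat(sprintf("  n = %s, deviance = %.4g, converged: %s\n",
              x$n, x$deviance, x$converged))
  cat(sprintf("  b0 = %.4f, b = %.4f per degC\n",
              x$coefficients[["b0"]], x$coefficients[["b"]]))
  cat(sprintf("  LT50 = %.2f degC (se %.2f)\n", x$lt50, x$lt50_se))
  invisible(x)
}

#' Median lethal temperature with its delta-method standard error
#'
#' @param fit A converged [fit_logistic_survival()] result with a non-zero
#'   slope.
#' @param slope_tol Slopes smaller than this in magnitude are treated as
#'   zero (LT50 undefined, median dose unstable).
#' @return Named vector `c(value, se)` in degC.
#' @export
lt50 <- function(fit, slope_tol = 1e-6) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (!isTRUE(fit$converged)) {
    stop("dose-response fit did not converge; LT50 not available",
         call. = FALSE)
  }
  b <- fit$coefficients[["b"]]
  if (!is.finite(b) || abs(b) < slope_tol) {
    stop("slope is (numerically) zero: the median lethal dose is undefined",
         call. = FALSE)
  }
  b0 <- fit$coefficients[["b0"]]
  grad <- c(-1 / b, b0 / b^2)
  se <- sqrt(pmax(drop(t(grad) %*% fit$vcov %*% grad), 0))
  c(value = -b0 / b, se = se)
}

#' Contrast two LT50 estimates from independent samples
#'
#' Difference of median lethal temperatures with a standard error combined
#' in quadrature (the two fits come from independent experiments) and the
#' corresponding z statistic.
#'
#' @param fit_a,fit_b Converged `dose_response_fit` objects; the difference
#'   is `lt50_a - lt50_b`.
#' @return Named vector `c(difference, se, z)`.
#' @export
compare_lt50 <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "dose_response_fit"),
            inherits(fit_b, "dose_response_fit"))
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged)) {
    stop("both dose-response fits must have converged", call. = FALSE)
  }
  diff <- fit_a$lt50 - fit_b$lt50
  se <- sqrt(fit_a$lt50_se^2 + fit_b$lt50_se^2)
  z <- if (se > 0) diff / se else if (diff == 0) 0 else Inf * sign(diff)
  c(difference = diff, se = se, z = z)
}
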