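# Independent textbook-formula oracles used to cross-check the package's
# statistical routines. These deliberately avoid lm()/t.test()/anova() and
# the package's own code paths.

# two-group Levene/Brown-Forsythe F from explicit sums of squares
levene_oracle <- function(a, b, center = stats::median) {
  za <- abs(a - center(a))
  zb <- abs(b - center(b))
  z <- c(za, zb)
  n <- length(z)
  zbar <- mean(z)
  ssb <- length(za) * (mean(za) - zbar)^2 + length(zb) * (mean(zb) - zbar)^2
  ssw <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  list(F = f, df = c(1L, n - 2L), p = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

# one-sample t from explicit moments
paired_t_oracle <- function(d) {
  n <- length(d)
  m <- mean(d)
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(mean_diff = m, t = t, df = n - 1L,
       p = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE))
}

# OLS through the normal equations (solve on crossproducts, not QR)
ols_oracle <- function(y, X) {
  b <- solve(crossprod(X), crossprod(X, y))
  r <- y - X %*% b
  list(coefficients = drop(b), rss = sum(r^2))
}

# sequential (Type-I) sums of squares by adding design blocks in order
seq_ss_oracle <- function(y, blocks) {
  X <- matrix(1, length(y), 1)
  rss_prev <- sum((y - mean(y))^2)
  ss <- numeric(length(blocks))
  for (i in seq_along(blocks)) {
    X <- cbind(X, blocks[[i]])
    fit <- ols_oracle(y, X)
    ss[i] <- rss_prev - fit$rss
    rss_prev <- fit$rss
  }
  list(ss = ss, rss = rss_prev)
}

# Bernoulli-logistic log-likelihood
logistic_loglik <- function(b0, b, x, y) {
  p <- stats::plogis(b0 + b * x)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# brute-force likelihood maximisation on iteratively refined (b0, b)
# lattices; final lattice spacing <= step_target in both coordinates
grid_logistic_mle <- function(x, y, b0_range = c(-120, 120),
                              b_range = c(-4, 1), step_target = 1e-3) {
  c0 <- mean(b0_range)
  c1 <- mean(b_range)
  w0 <- diff(b0_range) / 2
  w1 <- diff(b_range) / 2
  repeat {
    g0 <- seq(c0 - w0, c0 + w0, length.out = 41)
    g1 <- seq(c1 - w1, c1 + w1, length.out = 41)
    ll <- outer(g0, g1, Vectorize(function(a, b) logistic_loglik(a, b, x, y)))
    idx <- arrayInd(which.max(ll), dim(ll))
    c0 <- g0[idx[1]]
    c1 <- g1[idx[2]]
    s0 <- g0[2] - g0[1]
    s1 <- g1[2] - g1[1]
    if (s0 <= step_target && s1 <= step_target) {
      return(c(b0 = c0, b = c1, step0 = s0, step1 = s1))
    }
    # re-centre with a margin of several lattice steps
    w0 <- 4 * s0
    w1 <- 4 * s1
  }
}

# population moments of a truncated normal discretised to marks: the
# distribution simulate_gradient_trials() draws implied temperatures from
disc_truncnorm_moments <- function(mean, sd, lo, hi, marks) {
  k <- length(marks)
  cuts <- c(lo, (marks[-k] + marks[-1]) / 2, hi)
  z <- stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  p <- diff(stats::pnorm(cuts, mean, sd)) / z
  m <- sum(marks * p)
  v <- sum(marks^2 * p) - m^2
  list(mean = m, sd = sqrt(v), p = p)
}

# continuous truncated-normal mean by numeric integration
truncnorm_mean_oracle <- function(mean, sd, lo, hi) {
  z <- stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  stats::integrate(function(x) x * stats::dnorm(x, mean, sd) / z, lo, hi)$value
}

# shipped example configuration, used by several suites
example_config <- function() {
  read_run_config(system.file("extdata", "mpg_north.yaml",
                              package = "parasitherm"))
}
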