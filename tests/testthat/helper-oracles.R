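# Independent oracles used by the tests. Each deliberately takes a
# different computational route from the package implementation it checks.

# Dense-grid numerical posterior for the stage-1 model with p = 2
# coefficients: joint density of (beta1, beta2, log sigma^2) evaluated on a
# grid, normalised, then marginal means/sds by direct summation.
grid_posterior_oracle <- function(y, X, prior, nb = 81, ns = 81,
                                  span = 8, s2_span = 8) {
  stopifnot(ncol(X) == 2L)
  ls <- stats::lm.fit(X, y)
  df <- length(y) - 2L
  s2_hat <- sum(ls$residuals^2) / df
  se <- sqrt(diag(solve(crossprod(X))) * s2_hat)
  b_hat <- ls$coefficients
  g1 <- seq(b_hat[1] - span * se[1], b_hat[1] + span * se[1], length.out = nb)
  g2 <- seq(b_hat[2] - span * se[2], b_hat[2] + span * se[2], length.out = nb)
  g3 <- seq(log(s2_hat / s2_span), log(s2_hat * s2_span), length.out = ns)
  ee <- expand.grid(b1 = g1, b2 = g2, u = g3)
  sig2 <- exp(ee$u)
  rss <- colSums((y - X %*% rbind(ee$b1, ee$b2))^2)
  logp <- -length(y) / 2 * log(sig2) - rss / (2 * sig2) +
    dnorm(ee$b1, prior$eta_a, prior$eps_a, log = TRUE) +
    dnorm(ee$b2, prior$eta_b, prior$eps_b, log = TRUE) +
    (-(prior$nu + 1) * log(sig2) - prior$omega / sig2) +
    ee$u # jacobian of the log-variance grid
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  mom <- function(x) {
    m <- sum(w * x)
    c(mean = m, sd = sqrt(max(sum(w * x^2) - m^2, 0)))
  }
  list(b1 = mom(ee$b1), b2 = mom(ee$b2), sigma2 = mom(sig2))
}

# Brute-force marginal likelihood for the g-prior model by nested 1-D
# quadrature: the flat-prior intercept is integrated in closed form (a plain
# Gaussian integral), then beta (one slope) and sigma^2 numerically.
quadrature_log_marginal <- function(y, x = NULL, g = length(y)) {
  n <- length(y)
  if (is.null(x)) {
    # null model: integrate exp over sigma^2 only
    ybar <- mean(y)
    s_fun <- function(u) { # u = log sigma^2
      sig2 <- exp(u)
      -n / 2 * log(2 * pi * sig2) + 0.5 * log(2 * pi * sig2 / n) -
        sum((y - ybar)^2) / (2 * sig2) - log(sig2) + u
    }
    return(log_integrate_1d(s_fun, log(var(y) / 2000), log(var(y) * 2000)))
  }
  sxx <- sum((x - mean(x))^2)
  inner <- function(beta, sig2) {
    r <- y - x * beta
    rb <- mean(r)
    -n / 2 * log(2 * pi * sig2) + 0.5 * log(2 * pi * sig2 / n) -
      sum((r - rb)^2) / (2 * sig2) +
      dnorm(beta, 0, sqrt(g * sig2 / sxx), log = TRUE) -
      log(sig2)
  }
  b_scale <- sqrt(g * var(y) / sxx)
  outer_fun <- function(u) {
    sig2 <- exp(u)
    f <- function(b) inner(b, sig2)
    log_integrate_1d(f, -25 * b_scale, 25 * b_scale) + u
  }
  log_integrate_1d(outer_fun, log(var(y) / 2000), log(var(y) * 2000))
}

# log of integral of exp(logf) over [lo, hi] via adaptive quadrature with
# stable scaling.
log_integrate_1d <- function(logf, lo, hi) {
  probe <- seq(lo, hi, length.out = 201)
  k <- max(vapply(probe, logf, numeric(1)))
  val <- stats::integrate(function(t) exp(vapply(t, logf, numeric(1)) - k),
                          lo, hi, rel.tol = 1e-11, abs.tol = 0,
                          subdivisions = 400L)$value
  k + log(val)
}

# KR-20 via population item variances p*q (the (n-1)/n factors cancel in
# the ratio, so this must agree with the sample-variance alpha exactly).
kr20_oracle <- function(mat) {
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  k <- ncol(mat)
  p <- colMeans(mat)
  tot <- rowSums(mat)
  pop_var <- mean((tot - mean(tot))^2)
  k / (k - 1) * (1 - sum(p * (1 - p)) / pop_var)
}

# Deterministic stratified standard-normal sample (for tail-probability
# checks without Monte-Carlo flakiness).
stratified_normal <- function(m, mean = 0, sd = 1) {
  qnorm(stats::ppoints(m)) * sd + mean
}

# Minimal hand-built stage1_fit with point-mass (or supplied) draws.
fake_stage1_fit <- function(beta, sigma2, ref = "ASD", groups = character(0),
                            measure = "hads") {
  structure(list(beta = beta, sigma2 = sigma2, groups = groups, ref = ref,
                 measure = measure, covariates = character(0),
                 n = 0L, iterations = nrow(beta), burn_in = 0L, thin = 1L,
                 seed = 0L),
            class = "stage1_fit")
}

# A small, fast synthetic analysis cohort shared across tests.
small_test_cohort <- function(seed = 42) {
  g <- syndrome_groups()
  g$n <- pmax(6L, as.integer(round(g$n / 4)))
  cfg <- cohort_config(groups = g, missing_item_rate = 0)
  simulate_cohort(cfg, seed = seed)
}
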