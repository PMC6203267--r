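# Ordinal probit regression for the 0-7 stress score, fitted by
# truncated-normal data augmentation (the Albert-Chib scheme):
#
#   z_i | beta, gamma ~ N(x_i' beta, 1) truncated to (gamma_{y_i}, gamma_{y_i+1}]
#   beta | z          ~ N (vague N(0, 100 I) prior combined with the z's)
#   gamma_k | z, y    ~ Uniform on the admissible interval
#                       (max z in category k-1, min z in category k)
#
# Identification: unit latent variance and gamma_1 = 0; gamma_0 = -Inf,
# gamma_8 = +Inf. Categories with no observations get their cutpoints drawn
# uniformly over the prior-admissible interval between their neighbours
# (with a logged warning).

#' Fit an ordinal probit model by data augmentation
#'
#' @param cohort Data frame holding the response and model terms.
#' @param formula Model formula, e.g.
#'   `stress ~ group + wessex_max + child_age_c` (the intercept is kept;
#'   factor contrasts follow the usual `model.matrix()` rules).
#' @param iterations,burn_in,thin MCMC schedule. The plain cutpoint update
#'   mixes slowly, so the default is deliberately long.
#' @param seed Integer seed.
#' @param prior_sd Standard deviation of the vague normal prior on each
#'   slope (default 10).
#' @param n_categories Number of ordinal categories (default 8: scores 0-7).
#' @return A list of class `ordinal_fit`: `beta` (draws x coefficients),
#'   `gamma` (draws x interior cutpoints, first fixed at 0), `terms`
#'   metadata, schedule and seed. Every retained cutpoint vector is strictly
#'   increasing.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1) |>
#'   dplyr::mutate(child_age_c = child_age - 15, wessex_max = wessex == 9)
#' fit <- fit_ordinal_probit(cohort, stress ~ wessex_max + child_age_c,
#'                           iterations = 600, burn_in = 100)
fit_ordinal_probit <- function(cohort, formula,
                               iterations = 50000, burn_in = 5000,
                               thin = 10, seed = 1, prior_sd = 10,
                               n_categories = 8L) {
  cohort <- as.data.frame(cohort)
  mf <- stats::model.frame(formula, cohort, na.action = stats::na.omit)
  y <- as.integer(stats::model.response(mf))
  X <- model.matrix(attr(mf, "terms"), mf)
  if (any(y < 0L | y > n_categories - 1L))
    abort(sprintf("response must be integers in 0..%d", n_categories - 1L))
  if (length(unique(y)) < 2L)
    abort("need at least 2 distinct observed categories")
  if (!(iterations > burn_in && burn_in >= 0 && thin >= 1))
    abort("need iterations > burn_in >= 0 and thin >= 1")
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  n <- length(y)
  p <- ncol(X)

  counts <- tabulate(y + 1L, nbins = n_categories)
  if (any(counts == 0L))
    warning(sprintf("empty categor%s %s: cutpoints sampled from the admissible range",
                    if (sum(counts == 0L) > 1) "ies" else "y",
                    paste(which(counts == 0L) - 1L, collapse = ", ")),
            call. = FALSE)

  set.seed(as.integer(seed) %% 2147483647L)
  # cutpoint vector gam of length K+1 with gam[1] = -Inf, gam[2] = 0 (the
  # fixed cutpoint), gam[K+1] = +Inf; category c occupies (gam[c+1], gam[c+2]).
  # Interior cutpoints start at the empirical quantile positions (shifted so
  # the first is 0), which puts the slowly mixing cutpoint chain close to its
  # stationary region from the outset.
  K <- n_categories
  cum <- pmin(pmax(cumsum(counts)[-K] / n, 1 / (n + 1)), n / (n + 1))
  gam_init <- qnorm(cum)
  gam_init <- gam_init - gam_init[1]
  gam_init <- gam_init + cumsum(c(0, diff(gam_init) == 0)) * 1e-3 # keep strict
  gam <- c(-Inf, gam_init, Inf)
  beta <- rep(0, p)
  prior_prec <- diag(1 / prior_sd^2, p)
  XtX <- crossprod(X)
  cat_index <- lapply(seq_len(K), function(k) which(y == k - 1L))

  n_keep <- floor((iterations - burn_in) / thin)
  beta_out <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
  gam_out <- matrix(NA_real_, n_keep, K - 1L,
                    dimnames = list(NULL, paste0("gamma", seq_len(K - 1L))))
  kept <- 0L

  lo <- gam[y + 1L]; hi <- gam[y + 2L]
  for (it in seq_len(iterations)) {
    eta <- drop(X %*% beta)
    z <- rtruncnorm(n, mean = eta, sd = 1, lower = lo, upper = hi)

    Vinv <- prior_prec + XtX
    R <- chol(Vinv)
    m <- backsolve(R, forwardsolve(t(R), drop(crossprod(X, z))))
    beta <- m + backsolve(R, rnorm(p))

    # interior cutpoints gamma_2..gamma_{K-1} (gam[3..K]); gamma_1 stays 0
    for (k in seq(3L, length.out = max(0L, K - 2L))) {
      below <- cat_index[[k - 1L]] # category k-2, latent in (gam[k-1], gam[k])
      above <- cat_index[[k]]      # category k-1, latent in (gam[k], gam[k+1])
      lo_k <- if (length(below)) max(z[below]) else gam[k - 1L]
      hi_k <- if (length(above)) min(z[above]) else gam[k + 1L]
      lo_k <- max(lo_k, gam[k - 1L])
      hi_k <- min(hi_k, gam[k + 1L])
      if (!is.finite(lo_k)) lo_k <- hi_k - 10
      if (!is.finite(hi_k)) hi_k <- lo_k + 10
      gam[k] <- runif(1L, lo_k, hi_k)
    }
    lo <- gam[y + 1L]; hi <- gam[y + 2L]

    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      beta_out[kept, ] <- beta
      gam_out[kept, ] <- gam[2:K]
    }
  }

  structure(list(beta = beta_out, gamma = gam_out,
                 terms = attr(mf, "terms"),
                 xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
                 coef_names = colnames(X), n = n,
                 n_categories = K, iterations = iterations,
                 burn_in = burn_in, thin = thin, seed = seed),
            class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf(
    "<ordinal_fit> %d rows, %d coefficients, %d categories, %d retained draws\n",
    x$n, ncol(x$beta), x$n_categories, nrow(x$beta)))
  invisible(x)
}

#' @method tidy ordinal_fit
#' @export
tidy.ordinal_fit <- function(x, conf.level = 0.9, ...) {
  draws <- cbind(x$beta, x$gamma[, -1L, drop = FALSE])
  ci <- apply(draws, 2, central_interval, level = conf.level)
  tibble::tibble(term = colnames(draws),
                 estimate = colMeans(draws),
                 std.error = apply(draws, 2, sd),
                 conf.low = ci[1L, ], conf.high = ci[2L, ])
}

#' @method glance ordinal_fit
#' @export
glance.ordinal_fit <- function(x, ...) {
  tibble::tibble(nobs = x$n, n_coef = ncol(x$beta),
                 n_categories = x$n_categories,
                 retained = nrow(x$beta), iterations = x$iterations,
                 burn_in = x$burn_in, thin = x$thin)
}

# Resolve a covariate profile (one-row data frame) to the model's x vector.
profile_design <- function(fit, profile) {
  profile <- as.data.frame(profile)
  tt <- stats::delete.response(fit$terms)
  mf <- stats::model.frame(tt, profile, xlev = fit$xlevels)
  X <- model.matrix(tt, mf)
  if (!identical(colnames(X), fit$coef_names))
    abort("profile does not resolve to the fitted model terms")
  drop(X[1L, ])
}

#' Posterior category probabilities for a covariate profile
#'
#' `P(score = k | profile)` as the posterior average of
#' `Phi(gamma_{k+1} - x'beta) - Phi(gamma_k - x'beta)`; sums to 1.
#'
#' @param fit An `ordinal_fit`.
#' @param profile One-row data frame supplying every model term.
#' @return Named probability vector over scores `0..K-1`.
#' @export
category_probs <- function(fit, profile) {
  x <- profile_design(fit, profile)
  eta <- drop(fit$beta %*% x)
  K <- fit$n_categories
  bounds <- cbind(-Inf, fit$gamma, Inf) # draws x (K+1)
  cdf <- pnorm(bounds - eta)            # recycles eta down columns
  probs <- colMeans(cdf[, -1L, drop = FALSE] - cdf[, -(K + 1L), drop = FALSE])
  setNames(probs, as.character(0:(K - 1L)))
}

#' Posterior predictive median stress rating with 90% interval
#'
#' Inverts the posterior predictive category CDF: the median is the smallest
#' score with CDF >= 0.5 (so an exactly-split distribution reports the lower
#' median), and the central 90% interval the smallest scores with CDF >= 0.05
#' and >= 0.95.
#'
#' @param fit An `ordinal_fit`.
#' @param profile One-row data frame of covariate values.
#' @param level Interval level (default 0.9).
#' @return A tibble with `median`, `lower`, `upper` and the probability
#'   vector as a list column `probs`.
#' @export
posterior_median_rating <- function(fit, profile, level = 0.9) {
  probs <- category_probs(fit, profile)
  cdf <- cumsum(probs)
  scores <- as.integer(names(probs))
  a <- (1 - level) / 2
  q <- function(p) scores[which(cdf >= p - 1e-12)[1L]]
  tibble::tibble(median = q(0.5), lower = q(a), upper = q(1 - a),
                 probs = list(probs))
}

#' Bayesian posterior p-value for a group's child-age trend
#'
#' The smaller one-sided posterior tail probability of the group's total age
#' slope (global slope plus any group-specific interaction): values near 0
#' indicate a credible monotone trend, 0.5 no trend. The sign of the
#' posterior mean slope is reported alongside.
#'
#' @param fit An `ordinal_fit` whose model includes an age term.
#' @param group Group label (level of the `group` factor used in the fit);
#'   `NULL` for the reference group / global slope.
#' @param age_var Name of the age variable in the formula.
#' @param group_var Name of the grouping factor in the formula.
#' @return A tibble with `group`, `p_value`, `direction`, `mean_slope`.
#' @export
age_trend_pvalue <- function(fit, group = NULL, age_var = "child_age_c",
                             group_var = "group") {
  stopifnot(inherits(fit, "ordinal_fit"))
  cn <- fit$coef_names
  if (!age_var %in% cn)
    abort(sprintf("model has no `%s` term", age_var))
  slope <- fit$beta[, age_var]
  if (!is.null(group)) {
    inter <- c(paste0(group_var, group, ":", age_var),
               paste0(age_var, ":", group_var, group))
    hit <- inter[inter %in% cn]
    if (length(hit)) slope <- slope + fit$beta[, hit[1L]]
    else if (!group %in% (fit$xlevels[[group_var]] %||% group))
      abort(sprintf("age slope for group `%s` not identifiable from the model terms",
                    group))
  }
  m <- mean(slope)
  tibble::tibble(group = group %||% "(reference)",
                 p_value = min(mean(slope <= 0), mean(slope >= 0)),
                 direction = ifelse(m > 0, "increasing", "decreasing"),
                 mean_slope = m)
}

#' Posterior population stress table over covariate profiles
#'
#' Mirrors the published display: for each group, Wessex status and child
#' age, the posterior predictive category distribution with its median and
#' 90% interval.
#'
#' @param fit An `ordinal_fit` with terms `group`, `wessex_max`,
#'   `child_age_c` (centred age).
#' @param groups Group labels (default: the fitted factor levels).
#' @param wessex_max Indicator values to tabulate.
#' @param child_ages Child ages (years) to tabulate.
#' @param age_centre Centre used when the model's age term was built.
#' @return A tibble, one row per profile, with the probability of each score
#'   in wide columns `p0..p7` plus `median`, `lower`, `upper`.
#' @export
stress_profile_table <- function(fit, groups = NULL,
                                 wessex_max = c(0, 1),
                                 child_ages = c(8, 16),
                                 age_centre = 15) {
  groups <- groups %||% fit$xlevels$group
  grid <- tidyr::expand_grid(group = groups, wessex_max = wessex_max,
                             child_age = child_ages)
  rows <- purrr::pmap_dfr(grid, function(group, wessex_max, child_age) {
    prof <- tibble::tibble(group = group, wessex_max = wessex_max,
                           child_age_c = child_age - age_centre)
    rate <- posterior_median_rating(fit, prof)
    probs <- rate$probs[[1L]]
    out <- tibble::tibble(group = group, wessex_max = wessex_max,
                          child_age = child_age,
                          median = rate$median, lower = rate$lower,
                          upper = rate$upper)
    for (k in names(probs)) out[[paste0("p", k)]] <- probs[[k]]
    out
  })
  rows
}

#' Plot posterior population stress ratings by group
#'
#' @param object An `ordinal_fit` with `group`, `wessex_max` and
#'   `child_age_c` terms.
#' @param ... Passed to [stress_profile_table()].
#' @return A ggplot object: expected stress by group, one line per child
#'   age, for children below the Wessex maximum.
#' @method autoplot ordinal_fit
#' @export
autoplot.ordinal_fit <- function(object, ...) {
  tab <- stress_profile_table(object, wessex_max = 0, ...)
  tab$expected <- rowSums(
    as.matrix(tab[paste0("p", 0:(object$n_categories - 1L))]) %*%
      diag(0:(object$n_categories - 1L)))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$group, y = .data$expected,
                                    group = factor(.data$child_age),
                                    colour = factor(.data$child_age))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "expected stress score",
                  colour = "child age")
}
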