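# Stage-1 Bayesian linear regression: design construction, Gibbs sampling,
# posterior summaries and derived probabilities.

test_that("build_design uses reference-level coding", {
  cohort <- small_test_cohort()
  two <- dplyr::filter(cohort, group %in% c("ASD", "AS"))
  d <- build_design(two, "hads")
  expect_equal(colnames(d$X), c("ASD", "AS"))
  expect_true(all(d$X[, 1] == 1))

  full <- build_design(cohort, "pgs")
  expect_equal(ncol(full$X), 14L)
  expect_equal(colnames(full$X)[1], "ASD")
  # each non-reference row has exactly one indicator set; reference rows none
  ind <- full$X[, -1, drop = FALSE]
  expect_true(all(rowSums(ind) <= 1))
  expect_true(all(rowSums(ind)[cohort$group[!is.na(cohort$pgs)] == "ASD"] == 0))
  as_row <- which(cohort$group[!is.na(cohort$pgs)] == "AS")[1]
  expect_equal(sum(ind[as_row, ]), 1)
  expect_equal(unname(ind[as_row, "AS"]), 1)

  expect_error(build_design(cohort, "nope"), "unknown measure")
  expect_error(build_design(cohort, "hads", covariates = "shoe_size"),
               "unknown covariate")
})

test_that("rows with a missing response are dropped per measure", {
  cohort <- small_test_cohort()
  cohort$hads[1:5] <- NA
  d <- build_design(cohort, "hads")
  expect_equal(length(d$y), sum(!is.na(cohort$hads)))
})

test_that("with no data the sampler reproduces the prior", {
  empty <- list(y = numeric(0),
                X = matrix(numeric(0), nrow = 0, ncol = 1,
                           dimnames = list(NULL, "ASD")))
  prior <- default_priors("hads") # depression: N(7.6, 0.5^2)
  fit <- gibbs_linreg(empty, prior, iterations = 21000, burn_in = 1000,
                      seed = 2)
  expect_equal(mean(fit$beta[, 1]), 7.6, tolerance = 0.02)
  expect_equal(sd(fit$beta[, 1]), 0.5, tolerance = 0.02)
})

test_that("a near-degenerate difference prior pins the difference at zero", {
  cohort <- small_test_cohort()
  prior <- prior_spec(eta_a = 7.6, eps_a = 0.5, eps_b = 1e-6)
  fit <- fit_stage1(cohort, "hads", prior = prior, iterations = 1500,
                    burn_in = 500, seed = 3)
  expect_true(all(abs(fit$beta[, fit$groups]) < 1e-4))
})

test_that("Gibbs moments agree with a dense-grid numerical posterior", {
  set.seed(14)
  n <- 15
  X <- cbind(1, rbinom(n, 1, 0.5))
  colnames(X) <- c("ASD", "AS")
  y <- 7 + 1.2 * X[, 2] + rnorm(n, 0, 2)
  prior <- default_priors("hads")
  fit <- gibbs_linreg(list(y = y, X = X), prior, iterations = 12000,
                      burn_in = 2000, seed = 5)
  oracle <- grid_posterior_oracle(y, X, prior)
  ess <- apply(fit$beta, 2, bayeswell:::ess_draws)
  for (j in 1:2) {
    mcse <- sd(fit$beta[, j]) / sqrt(ess[j])
    expect_lt(abs(mean(fit$beta[, j]) - oracle[[j]]["mean"]), 3 * mcse)
    expect_lt(abs(sd(fit$beta[, j]) - oracle[[j]]["sd"]),
              3 * sd(fit$beta[, j]) / sqrt(2 * ess[j]))
  }
  s_ess <- bayeswell:::ess_draws(fit$sigma2)
  expect_lt(abs(mean(fit$sigma2) - oracle$sigma2["mean"]),
            3 * sd(fit$sigma2) / sqrt(s_ess))
})

test_that("sampler inputs are validated", {
  expect_error(gibbs_linreg(list(y = c(1, NA), X = cbind(1, c(1, 2))),
                            prior_spec()), "non-finite")
  expect_error(gibbs_linreg(list(y = rnorm(5), X = matrix(1, 5, 1)),
                            prior_spec(), iterations = 10, burn_in = 20),
               "iterations")
  expect_error(prior_spec(eps_a = -1), "eps_a")
})

test_that("chains are reproducible under a fixed seed", {
  cohort <- small_test_cohort()
  a <- fit_stage1(cohort, "pas5", iterations = 800, burn_in = 300, seed = 9)
  b <- fit_stage1(cohort, "pas5", iterations = 800, burn_in = 300, seed = 9)
  c <- fit_stage1(cohort, "pas5", iterations = 800, burn_in = 300, seed = 10)
  expect_identical(a$beta, b$beta)
  expect_false(identical(a$beta, c$beta))
  expect_equal(nrow(a$beta), 500L) # (iterations - burn_in) / thin
  expect_true(all(a$sigma2 > 0))
})

test_that("posterior summaries have nested intervals containing the mean", {
  cohort <- small_test_cohort()
  fit <- fit_stage1(cohort, "hads", iterations = 1500, burn_in = 500,
                    seed = 4)
  s <- summarise_posterior(fit)
  expect_true(all(s$lower_20 >= s$lower_50 & s$lower_50 >= s$lower_80 &
                    s$lower_80 >= s$lower_90))
  expect_true(all(s$upper_20 <= s$upper_50 & s$upper_50 <= s$upper_80 &
                    s$upper_80 <= s$upper_90))
  expect_true(all(s$mean >= s$lower_90 & s$mean <= s$upper_90))
  # absolute group means are reference + difference
  as_mean <- s$mean[s$term == "AS"]
  expect_equal(as_mean,
               s$mean[s$term == "ASD"] + s$mean[s$term == "diff_AS"],
               tolerance = 1e-10)
  expect_error(summarise_posterior(
    fake_stage1_fit(matrix(1, 50, 1, dimnames = list(NULL, "ASD")),
                    rep(1, 50))), "100")
})

test_that("interval endpoints match closed-form normal quantiles", {
  draws <- matrix(stratified_normal(1e6), ncol = 1,
                  dimnames = list(NULL, "ASD"))
  fit <- fake_stage1_fit(draws, rep(1, 1e6))
  s <- summarise_posterior(fit, levels = c(0.5, 0.9))
  expect_equal(s$lower_90[1], qnorm(0.05), tolerance = 0.01)
  expect_equal(s$upper_90[1], qnorm(0.95), tolerance = 0.01)
  # constant draws collapse every interval to a point
  cfit <- fake_stage1_fit(matrix(3, 200, 1, dimnames = list(NULL, "ASD")),
                          rep(1, 200))
  cs <- summarise_posterior(cfit)
  expect_equal(cs$lower_20[1], 3)
  expect_equal(cs$upper_90[1], 3)
})

test_that("prob_difference matches tail-probability closed forms", {
  mk <- function(diff_draws) {
    beta <- cbind(ASD = rep(0, length(diff_draws)), AS = diff_draws)
    fake_stage1_fit(beta, rep(1, length(diff_draws)), groups = "AS")
  }
  sym <- c(stratified_normal(5e4), -stratified_normal(5e4))
  expect_equal(prob_difference(mk(sym), "AS"), 0.5, tolerance = 1e-6)
  expect_equal(prob_difference(mk(abs(rnorm(1000)) + 0.01), "AS"), 1.0)
  # N(0.84 s, s^2) -> Phi(0.84) ~ 0.80
  expect_equal(prob_difference(mk(stratified_normal(2e5, mean = 0.84 * 2,
                                                    sd = 2)), "AS"),
               pnorm(0.84), tolerance = 0.005)
  expect_error(prob_difference(mk(rnorm(10)), "ASD"), "self-comparison")
})

test_that("prob_clinical matches normal-CDF closed forms", {
  point_fit <- function(mu, sigma) {
    fake_stage1_fit(matrix(mu, 500, 1, dimnames = list(NULL, "ASD")),
                    rep(sigma^2, 500))
  }
  expect_equal(prob_clinical(point_fit(5.61, 4.2), "ASD", cutoff = 7),
               pnorm((5.61 - 7) / 4.2), tolerance = 1e-12)
  expect_equal(prob_clinical(point_fit(7.12, 4.2), "ASD", cutoff = 7),
               pnorm((7.12 - 7) / 4.2), tolerance = 1e-12)
  # degenerate predictive at the cut-off: continuity convention 1/2
  expect_equal(prob_clinical(point_fit(7, 0), "ASD", cutoff = 7), 0.5)
  expect_error(prob_clinical(point_fit(5, 1), "ASD", cutoff = 30), "cutoff")
  # plugin and integrated modes agree for a point-mass variance
  expect_equal(prob_clinical(point_fit(5.61, 4.2), "ASD", method = "plugin"),
               prob_clinical(point_fit(5.61, 4.2), "ASD"))
})

test_that("similarity grouping clusters by posterior separation", {
  m <- 2000
  mk_fit <- function(means, s = 0.1) {
    set.seed(2024)
    draws <- vapply(means, function(mu) rnorm(m, mu, s), numeric(m))
    colnames(draws) <- c("ASD", paste0("G", seq_along(means[-1])))
    # convert absolute means to reference + differences
    beta <- cbind(draws[, 1],
                  draws[, -1, drop = FALSE] - draws[, 1])
    colnames(beta) <- colnames(draws)
    fake_stage1_fit(beta, rep(1, m), groups = colnames(draws)[-1])
  }
  # identical posteriors: one cluster
  same <- mk_fit(c(5, 5, 5))
  expect_equal(dplyr::n_distinct(group_by_similarity(same)$cluster), 1L)
  # two well-separated sets: exactly two clusters
  apart <- mk_fit(c(5, 5.01, 9, 9.02))
  cl <- group_by_similarity(apart)
  expect_equal(dplyr::n_distinct(cl$cluster), 2L)
  expect_equal(dplyr::n_distinct(cl$cluster[cl$posterior_mean < 7]), 1L)
  # threshold 1 can never be exceeded: everything merges
  expect_equal(dplyr::n_distinct(group_by_similarity(apart, 1.0)$cluster), 1L)
})

test_that("error-variance posterior tracks the generated noise level", {
  cfg_quiet <- cohort_config(missing_item_rate = 0)
  cfg_noisy <- cohort_config(missing_item_rate = 0)
  cfg_quiet$outcome_effects$hads$noise_sd <- 1
  cfg_noisy$outcome_effects$hads$noise_sd <- 4.2
  fit_q <- fit_stage1(simulate_cohort(cfg_quiet, seed = 11), "hads",
                      iterations = 1200, burn_in = 400, seed = 1)
  fit_n <- fit_stage1(simulate_cohort(cfg_noisy, seed = 11), "hads",
                      iterations = 1200, burn_in = 400, seed = 1)
  expect_lt(mean(fit_q$sigma2), mean(fit_n$sigma2))
})

test_that("draws persist to text and reload identically", {
  cohort <- small_test_cohort()
  fit <- fit_stage1(cohort, "hads", iterations = 600, burn_in = 100,
                    seed = 6, covariates = "child_age")
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  back <- read_draws(path)
  expect_equal(back$beta, fit$beta, tolerance = 1e-12)
  expect_equal(back$sigma2, fit$sigma2, tolerance = 1e-12)
  expect_identical(back$groups, fit$groups)
  expect_identical(back$ref, fit$ref)
  expect_identical(back$covariates, fit$covariates)
  expect_equal(back$seed, fit$seed)
})

test_that("tidy and glance return the broom-style schemas", {
  cohort <- small_test_cohort()
  fit <- fit_stage1(cohort, "pgs", iterations = 600, burn_in = 100, seed = 2)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low",
                     "conf.high"))
  expect_equal(nrow(td), ncol(fit$beta))
  gl <- glance(fit)
  expect_equal(gl$retained, 500L)
  expect_equal(gl$measure, "pgs")
  p <- autoplot(summarise_posterior(fit))
  expect_s3_class(p, "ggplot")
})
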