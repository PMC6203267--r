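# Stage 1: Bayesian linear regression of a continuous well-being measure on
# syndrome group (reference group = ASD), fitted by a two-block Gibbs
# sampler:
#   beta  | sigma^2, y ~ N(V m, V),  V = (S0^-1 + X'X/sigma^2)^-1,
#                               m = S0^-1 m0 + X'y/sigma^2
#   sigma^2 | beta, y ~ InvGamma(nu + n/2, omega + RSS/2)
# where (m0, S0) collect the independent normal priors on the reference
# level and the difference coefficients.

#' Build the stage-1 design matrix for one measure
#'
#' The reference group supplies the intercept; every other group gets a 0/1
#' difference indicator; requested covariates are appended. Rows with a
#' missing response (or missing covariate) are dropped, so different measures
#' may use different subsamples.
#'
#' @param cohort A scored cohort tibble (see [score_scales()]).
#' @param measure One of `"pgs"`, `"pas5"`, `"hads"` (or `"stress"`, used by
#'   the ordinal stage).
#' @param covariates Optional covariate columns: any of `"child_age"`,
#'   `"maternal_age"`, `"wessex"`, `"wessex_max"` (indicator for Wessex
#'   self-help at its maximum), `"child_male"`.
#' @param ref Reference group label (default `"ASD"`, else the first group).
#' @param wessex_max Maximum of the Wessex self-help scale used to derive
#'   `wessex_max`.
#' @return A list of class `design_matrix`: `y`, `X` (first column the
#'   intercept), `groups` (difference-column labels), `ref`, `measure`,
#'   `covariates`.
#' @export
build_design <- function(cohort, measure, covariates = character(),
                         ref = "ASD", wessex_max = 9L) {
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0L) abort("cohort is empty")
  if (!measure %in% measure_names())
    abort(sprintf("unknown measure `%s` (expected one of %s)", measure,
                  paste(measure_names(), collapse = ", ")))
  if (!measure %in% names(cohort))
    abort(sprintf("cohort lacks a `%s` column", measure))
  allowed <- c("child_age", "maternal_age", "wessex", "wessex_max",
               "child_male")
  bad <- setdiff(covariates, allowed)
  if (length(bad))
    abort(sprintf("unknown covariate(s): %s", paste(bad, collapse = ", ")))

  dat <- cohort
  if ("wessex_max" %in% covariates)
    dat$wessex_max <- as.numeric(dat$wessex == wessex_max)
  keep <- !is.na(dat[[measure]])
  for (v in covariates) keep <- keep & !is.na(dat[[v]])
  dat <- dat[keep, , drop = FALSE]

  groups_all <- unique(dat$group)
  if (!ref %in% groups_all) ref <- groups_all[1]
  others <- setdiff(groups_all, ref)

  y <- as.numeric(dat[[measure]])
  X <- matrix(1, nrow = nrow(dat), ncol = 1L,
              dimnames = list(NULL, ref))
  for (grp in others)
    X <- cbind(X, as.numeric(dat$group == grp))
  colnames(X) <- c(ref, others)
  for (v in covariates) X <- cbind(X, as.numeric(dat[[v]]))
  colnames(X) <- c(ref, others, covariates)

  structure(list(y = y, X = X, groups = others, ref = ref,
                 measure = measure, covariates = covariates),
            class = "design_matrix")
}

#' Two-block Gibbs sampler for the stage-1 linear model
#'
#' @param design A [build_design()] result, or any list with numeric `y` and
#'   matrix `X` (named columns). With zero data rows the sampler returns
#'   draws from the prior.
#' @param prior A [prior_spec()]; the first column of `X` takes the
#'   reference-level prior, all others the difference prior.
#' @param iterations,burn_in,thin MCMC schedule; `(iterations - burn_in) /
#'   thin` draws are retained.
#' @param seed Integer seed (fixed seed gives identical chains).
#' @return A list of class `stage1_fit` with `beta` (retained draws x
#'   coefficients), `sigma2`, the design metadata and the schedule.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' fit <- fit_stage1(cohort, "hads", iterations = 2000, burn_in = 500)
#' tidy(fit)
gibbs_linreg <- function(design, prior, iterations = 20000, burn_in = 2000,
                         thin = 1, seed = 1) {
  stopifnot(inherits(prior, "prior_spec"))
  y <- design$y
  X <- design$X
  if (!is.matrix(X)) X <- as.matrix(X)
  if (length(y) != nrow(X)) abort("length(y) must equal nrow(X)")
  if (length(y) && (any(!is.finite(y)) || any(!is.finite(X))))
    abort("non-finite values in y or X")
  if (!(iterations > burn_in && burn_in >= 0 && thin >= 1))
    abort("need iterations > burn_in >= 0 and thin >= 1")
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)

  n <- length(y)
  p <- ncol(X)
  labels <- colnames(X) %||% paste0("b", seq_len(p))
  m0 <- c(prior$eta_a, rep(prior$eta_b, p - 1L))
  s0 <- c(prior$eps_a, rep(prior$eps_b, p - 1L))
  prior_prec <- 1 / s0^2

  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  set.seed(as.integer(seed) %% 2147483647L)

  sigma2 <- if (n > 1) max(var(y), 1e-8) else 1
  n_keep <- floor((iterations - burn_in) / thin)
  beta_out <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, labels))
  sig_out <- numeric(n_keep)
  kept <- 0L

  for (it in seq_len(iterations)) {
    Vinv <- diag(prior_prec, p) + XtX / sigma2
    R <- chol(Vinv)
    m <- backsolve(R, forwardsolve(t(R), prior_prec * m0 + Xty / sigma2))
    beta <- m + backsolve(R, rnorm(p))
    resid <- if (n) y - drop(X %*% beta) else numeric(0)
    sigma2 <- 1 / rgamma(1L, shape = prior$nu + n / 2,
                         rate = prior$omega + sum(resid^2) / 2)
    sigma2 <- min(max(sigma2, 1e-300), 1e300)
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      beta_out[kept, ] <- beta
      sig_out[kept] <- sigma2
    }
  }

  structure(list(beta = beta_out, sigma2 = sig_out,
                 groups = design$groups %||% character(),
                 ref = design$ref %||% labels[1],
                 measure = design$measure %||% NA_character_,
                 covariates = design$covariates %||% character(),
                 n = n, iterations = iterations, burn_in = burn_in,
                 thin = thin, seed = seed),
            class = "stage1_fit")
}

#' @rdname gibbs_linreg
#' @inheritParams build_design
#' @export
fit_stage1 <- function(cohort, measure,
                       prior = default_priors(measure),
                       covariates = character(),
                       iterations = 20000, burn_in = 2000, thin = 1,
                       seed = 1, ref = "ASD") {
  design <- build_design(cohort, measure, covariates = covariates, ref = ref)
  gibbs_linreg(design, prior, iterations = iterations, burn_in = burn_in,
               thin = thin, seed = seed)
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat(sprintf(
    "<stage1_fit> %s: %d rows, %d coefficients, %d retained draws (seed %s)\n",
    x$measure %||% "?", x$n, ncol(x$beta), nrow(x$beta), format(x$seed)))
  invisible(x)
}

# Absolute group-mean draws: reference level plus the group's difference.
group_mean_draws <- function(fit, group) {
  stopifnot(inherits(fit, "stage1_fit"))
  if (group == fit$ref) return(fit$beta[, 1L])
  if (!group %in% fit$groups)
    abort(sprintf("group `%s` has no difference column", group))
  fit$beta[, 1L] + fit$beta[, group]
}
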