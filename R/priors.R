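# Prior specification for the stage-1 linear model.
#
# The model for each continuous measure y is
#   y ~ N(X beta, sigma^2),  X beta = beta_ref + beta_diff[group],
# with independent normal priors beta_ref ~ N(eta_a, eps_a^2) on the
# reference-group (ASD) level and beta_diff ~ N(eta_b, eps_b^2) on every
# syndrome-difference coefficient, and sigma^2 ~ InvGamma(nu, omega)
# parameterised by shape nu and scale omega directly (density proportional
# to (sigma^2)^-(nu+1) exp(-omega/sigma^2)); some software halves both,
# so `halved = TRUE` accepts that convention.

#' Specify stage-1 prior hyperparameters
#'
#' @param eta_a,eps_a Prior mean and standard deviation of the reference
#'   (ASD) level coefficient.
#' @param eta_b,eps_b Prior mean and sd of every syndrome-difference (and any
#'   covariate) coefficient.
#' @param nu,omega Inverse-gamma shape and scale for the error variance.
#' @param halved If `TRUE`, interpret `nu`/`omega` as the halved convention
#'   (shape `nu/2`, scale `omega/2`).
#' @return A list of class `prior_spec`.
#' @export
#' @examples
#' prior_spec(eta_a = 7.6, eps_a = 0.5) # the depression prior
prior_spec <- function(eta_a = 0, eps_a = 10, eta_b = 0, eps_b = 2,
                       nu = 0.001, omega = 0.001, halved = FALSE) {
  for (nm in c("eps_a", "eps_b", "nu", "omega")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop_bad_arg(nm, "must be a single positive number")
  }
  if (halved) { nu <- nu / 2; omega <- omega / 2 }
  structure(list(eta_a = eta_a, eps_a = eps_a, eta_b = eta_b, eps_b = eps_b,
                 nu = nu, omega = omega),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf(
    "<prior_spec> ref ~ N(%g, %g^2), diff ~ N(%g, %g^2), sigma^2 ~ IG(%g, %g)\n",
    x$eta_a, x$eps_a, x$eta_b, x$eps_b, x$nu, x$omega))
  invisible(x)
}

#' Study default priors per continuous measure
#'
#' The published hyperparameters: depression centred at 7.6 (sd 0.5),
#' positive gain at 21.0 (sd 2.0), positive affect at 15.0 (sd 0.5); all
#' syndrome differences centred at zero with sd 2, and a diffuse
#' InvGamma(0.001, 0.001) on the error variance.
#'
#' @param measure One of `"hads"`, `"pgs"`, `"pas5"`.
#' @return A [prior_spec()].
#' @export
default_priors <- function(measure = c("hads", "pgs", "pas5")) {
  measure <- match.arg(measure)
  switch(measure,
    hads = prior_spec(eta_a = 7.6,  eps_a = 0.5),
    pgs  = prior_spec(eta_a = 21.0, eps_a = 2.0),
    pas5 = prior_spec(eta_a = 15.0, eps_a = 0.5))
}
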