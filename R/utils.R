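# Shared numerical helpers.

#' Draw from a normal distribution truncated to an interval
#'
#' Inverse-CDF sampler, vectorised over all arguments. Used for child and
#' maternal ages (truncated below at 2 and 18 years respectively) and for the
#' latent utilities of the ordinal probit sampler.
#'
#' @param n Number of draws.
#' @param mean,sd Mean and standard deviation of the untruncated normal.
#' @param lower,upper Truncation bounds (may be `-Inf`/`Inf`).
#' @return Numeric vector of length `n`.
#' @keywords internal
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  # Guard the extreme-tail case where both CDF values round to 0 or 1:
  # fall back to the nearer bound, which is where essentially all mass sits.
  u <- runif(n, p_lo, p_hi)
  out <- qnorm(u, mean, sd)
  bad <- !is.finite(out)
  if (any(bad)) {
    out[bad] <- ifelse(p_lo[bad] >= 1 - 1e-15, lower[bad], upper[bad])
    out[bad] <- pmin(pmax(out[bad], lower[bad]), upper[bad])
  }
  out
}

# Round half away from zero (questionnaire convention for prorated scores;
# base round() rounds half to even).
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# Randomised rounding: integer with expectation exactly x.
random_round <- function(x) {
  f <- floor(x)
  f + rbinom(length(x), 1L, x - f)
}

#' Derive a per-stage seed from a master seed
#'
#' Stages of the pipeline are seeded independently so any one stage can be
#' re-run in isolation and still match the full run. The derivation hashes the
#' stage name onto the master seed and stays below 2^31.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage label, e.g. `"stage1:hads"`.
#' @return An integer seed.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1000003
  val <- ((abs(master_seed) %% 1000003) * 2017 + h * 7919) %% 2147483647
  as.integer(val)
}

# Internal: consistent error for bad user arguments.
stop_bad_arg <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "bayeswell_config_error")
}
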