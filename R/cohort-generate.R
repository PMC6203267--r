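# Synthetic cohort generation.
#
# Each dyad gets demographics drawn from its group's layout, then item-level
# questionnaire responses for the four scales. Items are produced by (i)
# drawing a continuous latent scale total around the configured latent mean,
# (ii) randomised rounding to an integer total (so the expected score equals
# the latent mean exactly away from the scale bounds), and (iii) spreading
# that total uniformly over the per-item capacity of the scale. The latent
# truth behind every cohort is returned alongside, for parameter-recovery
# testing of the downstream models.

#' Generate a synthetic cohort with item-level responses
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`. Two calls with the
#'   same config and seed return identical cohorts.
#' @return A list of class `cohort_sim` with elements:
#'   * `items`: a tibble, one row per dyad, with demographics
#'     (`group`, `child_age`, `maternal_age`, `child_male`, `wessex`,
#'     `respondent_role`, `scq`) and raw item columns `pgs_1..7` (original,
#'     unreversed coding), `pas5_1..5`, `hads_1..7`, `qrsf_1..7` (logical).
#'   * `truth`: the latent data-generating values (per-measure group means,
#'     covariate coefficients, noise sds, age centres).
#'   * `config`, `seed`.
#' @export
#' @examples
#' sim <- generate_cohort(cohort_config(), seed = 1)
#' nrow(sim$items) # 712
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_cohort_config(config)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed) %% 2147483647L)

  g <- config$groups
  n <- sum(g$n)
  idx <- rep(seq_len(nrow(g)), g$n)
  group <- g$group[idx]

  child_age <- round(rtruncnorm(n, g$child_age_mean[idx], g$child_age_sd[idx],
                                lower = 2), 1)
  maternal_age <- round(rtruncnorm(n, g$maternal_age_mean[idx],
                                   g$maternal_age_sd[idx], lower = 18), 1)
  child_male <- rbinom(n, 1L, g$p_male[idx])

  w_lo <- config$wessex_range[1]; w_hi <- config$wessex_range[2]
  at_max <- rbinom(n, 1L, g$p_wessex_max[idx]) == 1L
  wessex <- ifelse(at_max, w_hi,
                   sample(seq(w_lo, w_hi - 1L), n, replace = TRUE))

  respondent_role <- ifelse(
    runif(n) < config$p_nonmother,
    sample(c("father", "grandparent", "foster carer", "paid carer"),
           n, replace = TRUE),
    "mother")

  base_group <- g$group[1]
  scq <- rep(NA_real_, n)
  is_ref <- group == base_group
  if (any(is_ref)) {
    s <- config$scq
    scq[is_ref] <- round(rtruncnorm(sum(is_ref), s$mean, s$sd,
                                    lower = s$min, upper = s$max))
  }

  centres <- config$age_centres
  covs <- list(child_age = child_age - centres[["child"]],
               maternal_age = maternal_age - centres[["maternal"]],
               wessex_max = as.numeric(wessex == w_hi))

  defs <- scale_defs()
  items <- tibble::tibble(
    group = group, child_age = child_age, maternal_age = maternal_age,
    child_male = child_male, wessex = as.integer(wessex),
    respondent_role = respondent_role, scq = scq)

  truth <- list(age_centres = centres, measures = list())
  for (m in measure_names()) {
    eff <- config$outcome_effects[[m]]
    def <- defs[[m]]
    mu <- rep(eff$base, n)
    shift <- eff$shift
    if (length(shift)) {
      hit <- match(group, names(shift))
      mu <- mu + ifelse(is.na(hit), 0, shift[hit])
    }
    for (v in c("child_age", "maternal_age", "wessex_max"))
      mu <- mu + (eff[[v]] %||% 0) * covs[[v]]
    for (it in eff$interactions %||% list()) {
      in_set <- group %in% it$groups
      for (v in c("child_age", "maternal_age", "wessex_max"))
        if (!is.null(it[[v]])) mu <- mu + it[[v]] * covs[[v]] * in_set
    }
    mat <- draw_scale_items(mu, eff$noise_sd, def)
    if (config$missing_item_rate > 0) {
      drop <- matrix(runif(length(mat)) < config$missing_item_rate,
                     nrow = nrow(mat))
      mat[drop] <- NA
    }
    prefix <- if (m == "stress") "qrsf" else m
    colnames(mat) <- paste0(prefix, "_", seq_len(def$items))
    cols <- tibble::as_tibble(mat)
    if (m == "stress") cols <- dplyr::mutate(cols,
      dplyr::across(dplyr::everything(), ~ .x == 1))
    items <- dplyr::bind_cols(items, cols)
    truth$measures[[m]] <- list(
      group_mean = setNames(eff$base + c(0, ifelse(
        is.na(match(g$group[-1], names(shift))), 0,
        shift[match(g$group[-1], names(shift))])), g$group),
      base = eff$base, shift = shift,
      child_age = eff$child_age %||% 0,
      maternal_age = eff$maternal_age %||% 0,
      wessex_max = eff$wessex_max %||% 0,
      interactions = eff$interactions %||% list(),
      noise_sd = eff$noise_sd)
  }

  structure(list(items = items, truth = truth, config = config, seed = seed),
            class = "cohort_sim")
}

# Draw an n x k integer item matrix whose row sums have expectation mu
# (clamped to the feasible range [k*lo, k*hi]). Items are exchangeable:
# the integer total above the scale floor is spread by sampling without
# replacement from the per-item capacity slots.
draw_scale_items <- function(mu, noise_sd, def) {
  n <- length(mu)
  k <- def$items; lo <- def$lo; hi <- def$hi
  cap <- hi - lo
  t <- mu + rnorm(n, 0, noise_sd)
  t <- pmin(pmax(t, k * lo), k * hi)
  total <- random_round(t)
  total <- pmin(pmax(total, k * lo), k * hi)
  units <- total - k * lo
  slots <- rep.int(seq_len(k), rep.int(cap, k))
  mat <- matrix(lo, nrow = n, ncol = k)
  for (i in seq_len(n)) {
    u <- units[i]
    if (u > 0L)
      mat[i, ] <- lo + tabulate(slots[sample.int(length(slots), u)], k)
  }
  if (def$reversed) mat <- (lo + hi) - mat
  mat
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d dyads, %d groups (seed %s)\n",
              nrow(x$items), dplyr::n_distinct(x$items$group), format(x$seed)))
  invisible(x)
}

#' Simulate a scored, exclusion-filtered analysis cohort
#'
#' Convenience wrapper chaining [generate_cohort()], [score_scales()] and
#' [apply_exclusions()].
#'
#' @inheritParams generate_cohort
#' @param scq_cutoff SCQ screening cut-off passed to [apply_exclusions()].
#' @return A cohort tibble (see [score_scales()]) with an exclusion ledger
#'   attribute (see [exclusion_ledger()]).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed,
                            scq_cutoff = 15) {
  generate_cohort(config, seed = seed) |>
    score_scales() |>
    apply_exclusions(scq_cutoff = scq_cutoff)
}
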