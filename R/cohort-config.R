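# Configuration of the synthetic cohort generator.
#
# The defaults emulate the published study layout: 14 groups (an autism
# reference group, ASD, plus 13 rare genetic syndromes) totalling 712
# mother/child dyads, with group-specific child/maternal age distributions,
# child gender ratios and ability (Wessex self-help) profiles, and
# group-level latent effects on the four well-being scales.

#' Default per-group demographic layout
#'
#' One row per group (ASD first, as the reference level), giving the group
#' sample size, child and maternal age means/sds (years), proportion of male
#' children, and the probability that the child's Wessex self-help score is at
#' its maximum of 9 (the "able/partly able" ability contrast).
#'
#' @return A tibble with columns `group`, `n`, `child_age_mean`,
#'   `child_age_sd`, `maternal_age_mean`, `maternal_age_sd`, `p_male`,
#'   `p_wessex_max`.
#' @export
#' @examples
#' syndrome_groups()
syndrome_groups <- function() {
  tibble::tribble(
    ~group,  ~n, ~child_age_mean, ~child_age_sd, ~maternal_age_mean, ~maternal_age_sd, ~p_male, ~p_wessex_max,
    "ASD",   66L, 15.5,  6.5, 47.9,  6.8, 0.864, 0.892,
    "AS",    28L, 10.9,  3.3, 40.8,  4.9, 0.464, 0.143,
    "CdLS",  44L, 12.8,  8.2, 45.1,  9.1, 0.477, 0.409,
    "DS",    29L, 25.4, 11.8, 59.1, 12.3, 0.533, 0.900,
    "FXS",  102L, 15.0,  8.2, 45.6,  9.5, 1.000, 0.882,
    "PMS",   31L, 11.3,  8.4, 42.3,  9.9, 0.452, 0.226,
    "PWS",  101L, 12.2,  8.1, 44.5,  8.5, 0.523, 0.782,
    "RTT",   87L, 20.1, 10.2, 50.7,  9.2, 0.000, 0.100,
    "RTS",   47L, 21.3, 10.5, 49.8,  9.9, 0.553, 0.809,
    "SMS",   20L, 11.6,  7.2, 43.7,  8.5, 0.600, 0.600,
    "Soto",  38L, 15.3,  9.3, 46.3,  8.3, 0.684, 0.842,
    "TSC",   71L, 18.8, 10.7, 48.1, 10.3, 0.606, 0.662,
    "1p36",  26L, 10.9,  8.9, 41.2, 10.8, 0.786, 0.423,
    "8p23",  22L, 10.8,  5.5, 39.6,  6.1, 0.682, 0.591
  )
}

# Group-level latent shifts relative to the ASD reference, one named vector
# per measure, on the scale-score metric. Together with the bases below they
# reproduce the qualitative ordering of groups reported for each outcome.
default_group_shifts <- function() {
  list(
    pgs = c(AS = -0.11, CdLS = 0.00, DS = 0.76, FXS = 0.00, PMS = 1.32,
            PWS = -0.60, RTT = 1.05, RTS = 1.04, SMS = 0.04, Soto = 0.12,
            TSC = -0.02, `1p36` = -0.02, `8p23` = 0.23),
    pas5 = c(AS = 1.35, CdLS = 0.26, DS = 0.68, FXS = 0.52, PMS = 0.78,
             PWS = 0.40, RTT = 1.98, RTS = -0.18, SMS = 0.37, Soto = 0.28,
             TSC = 0.07, `1p36` = 0.38, `8p23` = 1.61),
    hads = c(AS = -1.09, CdLS = -0.20, DS = -2.33, FXS = -1.51, PMS = -0.99,
             PWS = -1.00, RTT = -2.42, RTS = -1.76, SMS = 0.54, Soto = -1.70,
             TSC = -1.24, `1p36` = -0.16, `8p23` = -2.30),
    stress = c(AS = -1.0, CdLS = -1.0, DS = -3.0, FXS = -2.0, PMS = -1.0,
               PWS = -2.0, RTT = -2.0, RTS = -1.0, SMS = 0.0, Soto = -2.0,
               TSC = -1.0, `1p36` = -1.0, `8p23` = -2.0)
  )
}

#' Default latent outcome-effect structure
#'
#' One entry per measure. `base` is the ASD-group latent mean of the scale
#' score; `shift` the per-group latent mean shift from ASD; `child_age`,
#' `maternal_age` (per year, centred at 15 and 47 years) and `wessex_max`
#' (indicator for self-help at maximum) are linear covariate effects;
#' `interactions` is a list of group-set-restricted extra effects;
#' `noise_sd` the sd of the latent residual on the scale-score metric.
#'
#' @return A named list with entries `pgs`, `pas5`, `hads`, `stress`.
#' @export
default_outcome_effects <- function() {
  shifts <- default_group_shifts()
  list(
    pgs = list(base = 21.66, shift = shifts$pgs,
               child_age = -0.05, maternal_age = -0.04, wessex_max = 0,
               interactions = list(
                 list(groups = c("DS", "RTS", "PMS", "RTT"), maternal_age = -0.04)
               ),
               noise_sd = 3.3),
    pas5 = list(base = 15.25, shift = shifts$pas5,
                child_age = 0, maternal_age = -0.06, wessex_max = 0,
                interactions = list(),
                noise_sd = 2.1),
    hads = list(base = 7.12, shift = shifts$hads,
                child_age = 0, maternal_age = 0, wessex_max = 0,
                interactions = list(
                  list(groups = c("AS", "FXS", "PWS", "TSC", "PMS"),
                       wessex_max = -1.8)
                ),
                noise_sd = 4.2),
    stress = list(base = 5.7, shift = shifts$stress,
                  child_age = 0.04, maternal_age = 0, wessex_max = -1.0,
                  interactions = list(
                    list(groups = c("Soto", "AS", "SMS"), child_age = -0.10)
                  ),
                  noise_sd = 1.5)
  )
}

#' Build a cohort generator configuration
#'
#' @param groups Per-group demographic tibble as returned by
#'   [syndrome_groups()] (ASD must be the first row; it is the reference
#'   group and the only one that receives Social Communication Questionnaire
#'   totals).
#' @param outcome_effects Latent effect structure as returned by
#'   [default_outcome_effects()].
#' @param missing_item_rate Probability that any single questionnaire item is
#'   left blank.
#' @param p_nonmother Probability a respondent is not the child's (adoptive)
#'   mother; such records are later removed by [apply_exclusions()]. Default 0
#'   so that the default cohort is the post-exclusion analysis sample.
#' @param wessex_range Integer range of the Wessex self-help score; only the
#'   "at maximum vs below" contrast is used analytically.
#' @param scq Generator for ASD-group SCQ totals: a list with `mean`, `sd`,
#'   `min`, `max` of a rounded truncated normal.
#' @param age_centres Centring constants (years) applied to child and maternal
#'   age before the covariate effects.
#' @param seed Default seed used by [generate_cohort()] when none is supplied.
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config()
#' sum(cfg$groups$n) # 712 dyads
cohort_config <- function(groups = syndrome_groups(),
                          outcome_effects = default_outcome_effects(),
                          missing_item_rate = 0.02,
                          p_nonmother = 0,
                          wessex_range = c(3L, 9L),
                          scq = list(mean = 22, sd = 5, min = 15, max = 39),
                          age_centres = c(child = 15, maternal = 47),
                          seed = 20181025) {
  cfg <- structure(
    list(groups = tibble::as_tibble(groups),
         outcome_effects = outcome_effects,
         missing_item_rate = missing_item_rate,
         p_nonmother = p_nonmother,
         wessex_range = as.integer(wessex_range),
         scq = scq,
         age_centres = age_centres,
         seed = seed),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d groups, %d dyads (reference: %s)\n",
              nrow(x$groups), sum(x$groups$n), x$groups$group[1]))
  cat(sprintf("  missing item rate %.3f, Wessex range %d-%d, seed %s\n",
              x$missing_item_rate, x$wessex_range[1], x$wessex_range[2],
              format(x$seed)))
  invisible(x)
}

# The scale dictionary: item count, per-item integer range, and whether the
# stored raw items are on a coding that must be reversed at scoring time
# (the Positive Gain Scale is administered so that low raw values signal
# more gain; the analysis score reverses items as value -> (lo+hi) - value).
scale_defs <- function() {
  list(
    pgs    = list(items = 7L, lo = 1L, hi = 5L, reversed = TRUE),
    pas5   = list(items = 5L, lo = 1L, hi = 5L, reversed = FALSE),
    hads   = list(items = 7L, lo = 0L, hi = 3L, reversed = FALSE),
    stress = list(items = 7L, lo = 0L, hi = 1L, reversed = FALSE)
  )
}

measure_names <- function() names(scale_defs())

validate_cohort_config <- function(cfg) {
  g <- cfg$groups
  req <- c("group", "n", "child_age_mean", "child_age_sd",
           "maternal_age_mean", "maternal_age_sd", "p_male", "p_wessex_max")
  missing_cols <- setdiff(req, names(g))
  if (length(missing_cols))
    stop_bad_arg("groups", paste("missing columns:",
                                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(g$group))
    stop_bad_arg("groups$group", "group labels must be unique")
  if (any(g$n < 1)) stop_bad_arg("groups$n", "all group sizes must be >= 1")
  for (col in c("p_male", "p_wessex_max"))
    if (any(g[[col]] < 0 | g[[col]] > 1))
      stop_bad_arg(paste0("groups$", col), "probabilities must lie in [0, 1]")
  if (any(g$child_age_sd <= 0) || any(g$maternal_age_sd <= 0))
    stop_bad_arg("groups age sd", "age standard deviations must be positive")
  if (cfg$missing_item_rate < 0 || cfg$missing_item_rate > 1)
    stop_bad_arg("missing_item_rate", "must lie in [0, 1]")
  if (cfg$p_nonmother < 0 || cfg$p_nonmother > 1)
    stop_bad_arg("p_nonmother", "must lie in [0, 1]")
  if (length(cfg$wessex_range) != 2L || cfg$wessex_range[1] >= cfg$wessex_range[2])
    stop_bad_arg("wessex_range", "must be two increasing integers")
  base_group <- g$group[1]
  for (m in measure_names()) {
    eff <- cfg$outcome_effects[[m]]
    if (is.null(eff))
      stop_bad_arg("outcome_effects", paste("missing measure:", m))
    if (!is.numeric(eff$noise_sd) || eff$noise_sd < 0)
      stop_bad_arg(paste0("outcome_effects$", m, "$noise_sd"),
                   "must be a non-negative number")
    extra <- setdiff(names(eff$shift), setdiff(g$group, base_group))
    if (length(extra))
      stop_bad_arg(paste0("outcome_effects$", m, "$shift"),
                   paste("unknown group(s):", paste(extra, collapse = ", ")))
  }
  invisible(cfg)
}

#' Read or write a cohort configuration as YAML
#'
#' The bundled default, `system.file("extdata", "default_cohort.yaml",
#' package = "bayeswell")`, reproduces the 14-group / 712-dyad layout.
#'
#' @param path File path.
#' @return `read_cohort_config()` returns a validated `cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$groups <- tibble::as_tibble(purrr::map(raw$groups, unlist))
  raw$groups$n <- as.integer(raw$groups$n)
  for (m in intersect(names(raw$outcome_effects), measure_names())) {
    eff <- raw$outcome_effects[[m]]
    eff$shift <- unlist(eff$shift)
    eff$interactions <- purrr::map(eff$interactions %||% list(), function(it) {
      it$groups <- unlist(it$groups)
      it
    })
    raw$outcome_effects[[m]] <- eff
  }
  cohort_config(groups = raw$groups,
                outcome_effects = raw$outcome_effects,
                missing_item_rate = raw$missing_item_rate,
                p_nonmother = raw$p_nonmother %||% 0,
                wessex_range = unlist(raw$wessex_range),
                scq = raw$scq,
                age_centres = unlist(raw$age_centres),
                seed = raw$seed)
}

#' @rdname read_cohort_config
#' @param config A `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  as_mappable <- function(x) {
    if (is.list(x)) lapply(x, as_mappable)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  out <- unclass(config)
  out$groups <- lapply(as.list(out$groups), unname)
  out$outcome_effects <- as_mappable(out$outcome_effects)
  out$age_centres <- as.list(out$age_centres)
  yaml::write_yaml(out, path)
  invisible(path)
}
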