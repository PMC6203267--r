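# Synthetic cohort generation, scale scoring, exclusion rules and
# internal-consistency statistics.

one_group_config <- function(base = list(pgs = 21, pas5 = 15, hads = 7,
                                         stress = 4),
                             noise = 0, missing = 0, n = 1L) {
  eff <- default_outcome_effects()
  for (m in names(eff)) {
    eff[[m]]$base <- base[[m]]
    eff[[m]]$shift <- setNames(numeric(0), character(0))
    eff[[m]]$child_age <- 0
    eff[[m]]$maternal_age <- 0
    eff[[m]]$wessex_max <- 0
    eff[[m]]$interactions <- list()
    eff[[m]]$noise_sd <- noise
  }
  g <- syndrome_groups()[1, ]
  g$n <- as.integer(n)
  cohort_config(groups = g, outcome_effects = eff,
                missing_item_rate = missing)
}

test_that("default configuration yields the full study layout", {
  cfg <- cohort_config()
  expect_equal(sum(cfg$groups$n), 712L)
  expect_equal(nrow(cfg$groups), 14L)
  expect_identical(cfg$groups$group[1], "ASD")
  sim <- generate_cohort(cfg, seed = 1)
  expect_equal(nrow(sim$items), 712L)
  expect_equal(sort(unique(sim$items$group)), sort(cfg$groups$group))
  expect_equal(as.vector(table(sim$items$group)[cfg$groups$group]),
               cfg$groups$n)
  expect_true(all(sim$items$child_age >= 2))
  expect_true(all(sim$items$maternal_age >= 18))
  # SCQ totals only in the reference group
  expect_true(all(is.na(sim$items$scq[sim$items$group != "ASD"])))
  expect_true(all(!is.na(sim$items$scq[sim$items$group == "ASD"])))
})

test_that("generation is a deterministic function of (config, seed)", {
  cfg <- cohort_config()
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  c <- generate_cohort(cfg, seed = 8)
  expect_identical(a$items, b$items)
  expect_false(isTRUE(all.equal(a$items, c$items)))
})

test_that("a single noiseless dyad reproduces the configured latent means", {
  cfg <- one_group_config()
  cohort <- score_scales(generate_cohort(cfg, seed = 3))
  expect_equal(cohort$pgs, 21L)
  expect_equal(cohort$pas5, 15L)
  expect_equal(cohort$hads, 7L)
  expect_equal(cohort$stress, 4L)
})

test_that("invalid configuration fields are rejected by name", {
  g <- syndrome_groups()
  g$p_male[2] <- 1.4
  expect_error(cohort_config(groups = g), "p_male")
  expect_error(cohort_config(missing_item_rate = 2), "missing_item_rate")
  eff <- default_outcome_effects()
  eff$hads$shift <- c(eff$hads$shift, nosuch = 1)
  expect_error(cohort_config(outcome_effects = eff), "unknown group")
})

make_items <- function(pgs = rep(1, 7), pas5 = rep(3, 5), hads = rep(1, 7),
                       qrsf = rep(TRUE, 7)) {
  row <- c(list(group = "ASD", child_age = 10, maternal_age = 40,
                child_male = 1L, wessex = 9L, respondent_role = "mother",
                scq = 20),
           setNames(as.list(pgs), paste0("pgs_", 1:7)),
           setNames(as.list(pas5), paste0("pas5_", 1:5)),
           setNames(as.list(hads), paste0("hads_", 1:7)),
           setNames(as.list(qrsf), paste0("qrsf_", 1:7)))
  tibble::as_tibble(row)
}

test_that("scale scoring matches the documented rules", {
  # HADS range endpoints
  expect_equal(score_scales(make_items(hads = rep(0, 7)))$hads, 0L)
  expect_equal(score_scales(make_items(hads = rep(3, 7)))$hads, 21L)
  # stress counts the TRUE responses
  sc <- score_scales(make_items(qrsf = c(rep(TRUE, 6), FALSE)))
  expect_equal(sc$stress, 6L)
  # raw all-1 positive-gain items reverse-code to the maximum: brute-force
  # reversal 1<->5, 2<->4 summed over 7 items
  raw <- rep(1, 7)
  expect_equal(score_scales(make_items(pgs = raw))$pgs,
               as.integer(sum(6 - raw)))
  expect_equal(score_scales(make_items(pgs = rep(5, 7)))$pgs, 7L)
})

test_that("partial scales are prorated at >= 75% and missing below", {
  # 6 of 7 answered (85.7%): prorated mean x 7, rounded half up
  it <- make_items(hads = c(2, 2, 2, 2, 2, 1, NA))
  sc <- score_scales(it)
  expect_equal(sc$hads, as.integer(round(11 / 6 * 7))) # 12.83 -> 13
  expect_equal(sc$hads_completion, 6 / 7)
  # 5 of 7 (71.4%): below threshold, flagged missing (never zero)
  it2 <- make_items(hads = c(0, 0, 0, 0, 0, NA, NA))
  expect_true(is.na(score_scales(it2)$hads))
  # all missing: still missing
  it3 <- make_items(hads = rep(NA_real_, 7))
  expect_true(is.na(score_scales(it3)$hads))
})

test_that("item values outside the scale range are rejected", {
  expect_error(score_scales(make_items(hads = c(4, rep(1, 6)))), "hads")
  expect_error(score_scales(make_items(pgs = c(0, rep(2, 6)))), "pgs")
})

test_that("each exclusion rule fires once on a toy table and boundaries hold", {
  base <- score_scales(dplyr::bind_rows(
    make_items(), make_items(), make_items(), make_items(), make_items()))
  base$respondent_role <- c("mother", "father", "mother", "mother", "mother")
  base$child_age <- c(10, 10, 1, 10, 10)
  base$scq <- c(20, 20, 20, 14, 15)
  out <- apply_exclusions(base)
  ledger <- exclusion_ledger(out)
  expect_equal(nrow(out), 2L)
  expect_equal(ledger$n_excluded[ledger$rule == "non_mother"], 1L)
  expect_equal(ledger$n_excluded[ledger$rule == "child_under_2"], 1L)
  # SCQ boundary: "below the cut-off" excludes 14, retains exactly 15
  expect_equal(ledger$n_excluded[ledger$rule == "scq_below_cutoff"], 1L)
  expect_true(15 %in% out$scq && !14 %in% out$scq)
  expect_equal(sum(ledger$n_excluded), nrow(base) - nrow(out))
})

test_that("completion-based exclusion uses the 75% boundary per scale", {
  rows <- dplyr::bind_rows(
    make_items(hads = c(rep(1, 5), NA, NA)), # 5/7 = 71.4% -> excluded
    make_items(hads = c(rep(1, 6), NA)))     # 6/7 = 85.7% -> retained
  sc <- score_scales(rows)
  out <- apply_exclusions(sc)
  expect_equal(nrow(out), 1L)
  expect_equal(out$hads_completion, 6 / 7)
  ledger <- exclusion_ledger(out)
  expect_equal(ledger$n_excluded[ledger$rule == "incomplete_scales"], 1L)
})

test_that("empty input gives an empty table with a zeroed ledger", {
  sc <- score_scales(make_items())[0, ]
  out <- apply_exclusions(sc)
  expect_equal(nrow(out), 0L)
  expect_true(all(exclusion_ledger(out)$n_excluded == 0L))
})

test_that("scored scales stay inside their closed ranges", {
  cfg <- cohort_config(missing_item_rate = 0.1)
  cohort <- score_scales(generate_cohort(cfg, seed = 21))
  expect_true(all(dplyr::between(cohort$pgs, 7, 35), na.rm = TRUE))
  expect_true(all(dplyr::between(cohort$pas5, 5, 25), na.rm = TRUE))
  expect_true(all(dplyr::between(cohort$hads, 0, 21), na.rm = TRUE))
  expect_true(all(dplyr::between(cohort$stress, 0, 7), na.rm = TRUE))
  expect_true(all(cohort$wessex <= 9))
})

test_that("group score means converge to the configured latent means", {
  # zero noise, zero missingness: only randomised rounding remains, so the
  # sample mean should sit within a few thousandths of the latent mean
  cfg <- one_group_config(base = list(pgs = 21.66, pas5 = 15.25,
                                      hads = 7.12, stress = 4.3),
                          n = 4000L)
  sc <- score_scales(generate_cohort(cfg, seed = 5))
  expect_equal(mean(sc$pgs), 21.66, tolerance = 0.01)
  expect_equal(mean(sc$hads), 7.12, tolerance = 0.01)
  expect_equal(mean(sc$stress), 4.3, tolerance = 0.01)
})

test_that("cronbach_alpha matches its closed-form cases and KR-20", {
  x <- rnorm(40)
  expect_equal(cronbach_alpha(cbind(x, x)), 1)
  # three orthogonal equal-variance items: sum of item variances equals the
  # total variance, so alpha is exactly zero
  m <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1), c(1, -1, -1, 1))
  expect_equal(cronbach_alpha(m), 0)
  # dichotomous items: alpha equals the independently computed KR-20
  set.seed(8)
  p <- stats::plogis(rnorm(60))
  dich <- vapply(1:7, function(j) rbinom(60, 1, p), numeric(60))
  expect_equal(cronbach_alpha(dich), kr20_oracle(dich), tolerance = 1e-12)
  # degenerate input signalled explicitly
  expect_error(cronbach_alpha(matrix(1, 5, 3)), class = "bayeswell_degenerate_error")
  expect_error(cronbach_alpha(matrix(rnorm(4), 2, 2)[, 1, drop = FALSE]),
               "2 items")
})

test_that("configuration round-trips through YAML", {
  cfg <- cohort_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, path)
  cfg2 <- read_cohort_config(path)
  expect_equal(cfg2$groups, cfg$groups)
  expect_equal(cfg2$outcome_effects, cfg$outcome_effects)
  expect_equal(cfg2$wessex_range, cfg$wessex_range)
  a <- generate_cohort(cfg, seed = 4)
  b <- generate_cohort(cfg2, seed = 4)
  expect_identical(a$items, b$items)
})

test_that("the bundled default configuration reproduces the study layout", {
  path <- system.file("extdata", "default_cohort.yaml", package = "bayeswell")
  cfg <- read_cohort_config(path)
  expect_equal(sum(cfg$groups$n), 712L)
  expect_equal(cfg$groups, syndrome_groups())
})
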