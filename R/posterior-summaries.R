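# Posterior summaries and derived quantities for stage-1 fits: central
# credible intervals at nested levels, probabilities of difference from the
# reference group, posterior predictive clinical-depression risk, and the
# similarity grouping used to shade the per-group caterpillar displays.

central_interval <- function(draws, level) {
  a <- (1 - level) / 2
  unname(quantile(draws, c(a, 1 - a), names = FALSE, type = 7))
}

#' Summarise a stage-1 posterior
#'
#' Reports, per quantity, the posterior mean and central credible intervals
#' at the requested levels. Group rows are absolute means (reference level
#' plus the group's difference coefficient); difference coefficients,
#' covariate coefficients and the error variance are also included.
#'
#' @param fit A `stage1_fit`.
#' @param levels Credible levels; the defaults mirror the 20/50/80% display
#'   bands plus the 90% reporting interval.
#' @return A tibble of class `stage1_summary` with columns `term`, `kind`
#'   (`group_mean`, `difference`, `covariate`, `variance`), `mean`, and
#'   `lower_XX`/`upper_XX` per level.
#' @export
summarise_posterior <- function(fit, levels = c(0.2, 0.5, 0.8, 0.9)) {
  stopifnot(inherits(fit, "stage1_fit"))
  if (nrow(fit$beta) < 100L)
    abort("summarise_posterior() needs at least 100 retained draws")
  levels <- sort(levels)

  quantities <- c(
    setNames(lapply(c(fit$ref, fit$groups), function(g)
      group_mean_draws(fit, g)), c(fit$ref, fit$groups)),
    setNames(lapply(fit$groups, function(g) fit$beta[, g]),
             if (length(fit$groups)) paste0("diff_", fit$groups) else NULL),
    setNames(lapply(fit$covariates, function(v) fit$beta[, v]),
             fit$covariates),
    list(sigma2 = fit$sigma2))
  kind <- c(rep("group_mean", 1L + length(fit$groups)),
            rep("difference", length(fit$groups)),
            rep("covariate", length(fit$covariates)),
            "variance")

  out <- tibble::tibble(term = names(quantities), kind = kind,
                        mean = vapply(quantities, mean, numeric(1),
                                      USE.NAMES = FALSE))
  for (lv in levels) {
    ci <- vapply(quantities, central_interval, numeric(2), level = lv)
    out[[sprintf("lower_%d", round(100 * lv))]] <- unname(ci[1L, ])
    out[[sprintf("upper_%d", round(100 * lv))]] <- unname(ci[2L, ])
  }
  structure(out, levels = levels, measure = fit$measure, ref = fit$ref,
            class = c("stage1_summary", class(out)))
}

#' Posterior probability that a group differs from the reference
#'
#' The larger one-sided tail probability of the group's difference
#' coefficient, `max(P(diff > 0), P(diff < 0))`: near 0.5 when the group is
#' posterior-equivalent to the reference, 1 when the two are almost surely
#' different.
#'
#' @param fit A `stage1_fit`.
#' @param group A non-reference group label.
#' @return A number in (approximately) \[0.5, 1\].
#' @export
prob_difference <- function(fit, group) {
  stopifnot(inherits(fit, "stage1_fit"))
  if (group == fit$ref)
    abort("no self-comparison: `group` is the reference group")
  if (!group %in% fit$groups)
    abort(sprintf("group `%s` has no difference column", group))
  d <- fit$beta[, group]
  max(mean(d > 0), mean(d < 0))
}

#' Posterior predictive probability of clinical depression
#'
#' For the depression scale, the probability that a new mother in `group`
#' scores above the clinical cut-off: `P(y_new > cutoff)` with
#' `y_new | beta, sigma^2 ~ N(mu_group, sigma^2)`, averaged over the
#' posterior draws (`method = "integrate"`), or with the posterior-mean
#' predictive sd plugged in (`method = "plugin"`). A degenerate predictive
#' exactly at the cut-off counts 1/2 by the continuity convention.
#'
#' @param fit A `stage1_fit` for the depression measure.
#' @param group Group label (the reference group is allowed here).
#' @param cutoff Clinical cut-off on the 0-21 scale (scores above it are
#'   clinically significant; default 7).
#' @param method `"integrate"` (average over sigma^2 draws) or `"plugin"`.
#' @return A probability in \[0, 1\].
#' @export
prob_clinical <- function(fit, group, cutoff = 7,
                          method = c("integrate", "plugin")) {
  stopifnot(inherits(fit, "stage1_fit"))
  method <- match.arg(method)
  if (cutoff < 0 || cutoff > 21)
    abort("cutoff must lie in [0, 21]")
  mu <- group_mean_draws(fit, group)
  sigma <- sqrt(fit$sigma2)
  if (method == "plugin") sigma <- rep(sqrt(mean(fit$sigma2)), length(mu))
  z <- mu - cutoff
  p <- ifelse(sigma > 0, pnorm(z / sigma),
              ifelse(z > 0, 1, ifelse(z < 0, 0, 0.5)))
  mean(p)
}

#' Partition groups into posterior-similarity clusters
#'
#' Greedy agglomeration over groups ordered by posterior mean: a group joins
#' the current cluster while its pairwise probability of difference with
#' every member stays below `threshold`; otherwise it starts a new cluster.
#' Pairwise probabilities use the difference of absolute group-mean draws,
#' so the result is invariant to the reference-group coding.
#'
#' @param fit A `stage1_fit` (all groups summarised from this common fit).
#' @param threshold Probability-of-difference threshold (default 0.9).
#' @return A tibble with `group`, `posterior_mean`, `cluster` (1-based, in
#'   ascending order of cluster mean).
#' @export
group_by_similarity <- function(fit, threshold = 0.9) {
  stopifnot(inherits(fit, "stage1_fit"))
  groups <- c(fit$ref, fit$groups)
  draws <- vapply(groups, function(g) group_mean_draws(fit, g),
                  numeric(nrow(fit$beta)))
  means <- colMeans(draws)
  ord <- order(means)
  cluster <- integer(length(groups))
  current <- integer(0)
  id <- 0L
  for (i in ord) {
    joins <- length(current) > 0L &&
      (threshold >= 1 || # a tail probability cannot exceed 1: always merge
         all(vapply(current, function(j) {
           d <- draws[, i] - draws[, j]
           max(mean(d > 0), mean(d < 0)) < threshold
         }, logical(1))))
    if (!joins) { id <- id + 1L; current <- integer(0) }
    cluster[i] <- id
    current <- c(current, i)
  }
  tibble::tibble(group = groups[ord], posterior_mean = means[ord],
                 cluster = cluster[ord])
}

#' @method tidy stage1_fit
#' @export
tidy.stage1_fit <- function(x, conf.level = 0.9, ...) {
  draws <- x$beta
  ci <- apply(draws, 2, central_interval, level = conf.level)
  tibble::tibble(term = colnames(draws),
                 estimate = colMeans(draws),
                 std.error = apply(draws, 2, sd),
                 conf.low = ci[1L, ], conf.high = ci[2L, ])
}

#' @method glance stage1_fit
#' @export
glance.stage1_fit <- function(x, ...) {
  tibble::tibble(measure = x$measure %||% NA_character_,
                 nobs = x$n, n_coef = ncol(x$beta),
                 retained = nrow(x$beta),
                 iterations = x$iterations, burn_in = x$burn_in,
                 thin = x$thin,
                 sigma = sqrt(mean(x$sigma2)),
                 ess_min = min(apply(x$beta, 2, ess_draws)))
}

# Initial-monotone-sequence style effective sample size from the empirical
# autocorrelations (adequate for the simple trace diagnostics kept here).
ess_draws <- function(draws) {
  n <- length(draws)
  if (sd(draws) == 0) return(n)
  rho <- drop(stats::acf(draws, lag.max = min(100L, n - 1L),
                         plot = FALSE)$acf)[-1]
  pos <- which(rho < 0.05)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' Caterpillar plot of a stage-1 posterior summary
#'
#' Group posterior means with nested 20/50/80% (and any other configured)
#' credible bands, ordered by posterior mean, with a dashed line at the
#' all-group mean.
#'
#' @param object A `stage1_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stage1_summary
#' @export
autoplot.stage1_summary <- function(object, ...) {
  levels <- attr(object, "levels")
  dat <- dplyr::filter(object, .data$kind == "group_mean") |>
    dplyr::mutate(term = factor(.data$term,
                                levels = .data$term[order(.data$mean)]))
  long <- purrr::map_dfr(levels, function(lv) {
    tibble::tibble(term = dat$term, level = paste0(round(100 * lv), "%"),
                   lower = dat[[sprintf("lower_%d", round(100 * lv))]],
                   upper = dat[[sprintf("upper_%d", round(100 * lv))]])
  })
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$term)) +
    ggplot2::geom_segment(
      data = long,
      ggplot2::aes(x = .data$lower, xend = .data$upper,
                   y = .data$term, yend = .data$term,
                   linetype = .data$level)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$mean), size = 2) +
    ggplot2::geom_vline(xintercept = mean(dat$mean), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = attr(object, "measure") %||% "posterior mean",
                  y = NULL, linetype = "credible level")
}

#' Persist or reload stage-1 posterior draws as plain text
#'
#' Writes a CSV of the retained draws preceded by `#key: value` metadata
#' lines (seed, schedule, measure, reference group).
#'
#' @param fit A `stage1_fit`.
#' @param path Output file.
#' @return `write_draws()` returns `path` invisibly; `read_draws()` returns
#'   a `stage1_fit`.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "stage1_fit"))
  meta <- c(measure = fit$measure %||% "", ref = fit$ref,
            groups = paste(fit$groups, collapse = "|"),
            covariates = paste(fit$covariates, collapse = "|"),
            n = fit$n, iterations = fit$iterations, burn_in = fit$burn_in,
            thin = fit$thin, seed = fit$seed)
  dat <- tibble::as_tibble(fit$beta)
  dat$sigma2 <- fit$sigma2
  csv <- strsplit(readr::format_csv(dat), "\n", fixed = TRUE)[[1]]
  writeLines(c(sprintf("#%s: %s", names(meta), meta), csv), path)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- strsplit(sub("^#", "", lines[meta_lines]), ": ", fixed = TRUE)
  meta <- setNames(vapply(meta, function(x) x[2] %||% "", character(1)),
                   vapply(meta, `[`, character(1), 1))
  dat <- readr::read_csv(I(lines[-meta_lines]), show_col_types = FALSE)
  split_bar <- function(x) if (is.na(x) || x == "") character(0) else
    strsplit(x, "|", fixed = TRUE)[[1]]
  structure(list(
    beta = as.matrix(dat[setdiff(names(dat), "sigma2")]),
    sigma2 = dat$sigma2,
    groups = split_bar(meta[["groups"]]), ref = meta[["ref"]],
    measure = if (meta[["measure"]] == "") NA_character_ else meta[["measure"]],
    covariates = split_bar(meta[["covariates"]]),
    n = as.integer(meta[["n"]]),
    iterations = as.integer(meta[["iterations"]]),
    burn_in = as.integer(meta[["burn_in"]]),
    thin = as.integer(meta[["thin"]]),
    seed = as.numeric(meta[["seed"]])), class = "stage1_fit")
}
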