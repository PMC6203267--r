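# Bayesian Model Averaging by exact enumeration.
#
# Candidate predictors (syndrome-partition indicators, CART-derived
# dichotomies, and their interactions) define a model space of all
# admissible subsets; every model is scored by its closed-form marginal
# likelihood under a Zellner g-prior on the slopes (reference priors on the
# intercept and error variance) and a uniform prior over admissible models.
# For a model M with k slopes, centred design, coefficient of
# determination R2 and total sum of squares TSS:
#
#   log m(y | M) = lgamma((n-1)/2) - ((n-1)/2) log(pi) - (1/2) log(n)
#                  - ((n-1)/2) log(TSS)
#                  + ((n-1-k)/2) log(1+g) - ((n-1)/2) log(1 + g (1 - R2))
#
# Posterior model probabilities are proportional to these marginals; the
# inclusion probability of a predictor is the summed probability of the
# models containing it, and model-averaged coefficient moments mix the
# per-model conditional posteriors (slope posterior mean g/(1+g) * OLS).

#' Closed-form log marginal likelihood under the Zellner g-prior
#'
#' @param y Response vector.
#' @param X Predictor matrix for the model's slopes (no intercept column;
#'   may have zero columns for the null model).
#' @param g The g-prior scale; default `length(y)` (unit information).
#' @return The log marginal likelihood (absolute scale, so values are
#'   comparable across models on the same `y`).
#' @export
log_marginal <- function(y, X = NULL, g = length(y)) {
  n <- length(y)
  yc <- y - mean(y)
  tss <- sum(yc^2)
  if (tss <= 0) abort("log_marginal() undefined: y has zero variance")
  base <- lgamma((n - 1) / 2) - ((n - 1) / 2) * log(pi) - 0.5 * log(n) -
    ((n - 1) / 2) * log(tss)
  if (is.null(X) || NCOL(X) == 0L) return(base)
  X <- as.matrix(X)
  k <- ncol(X)
  if (n <= k + 1L) abort("need n > number of selected columns + 1")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrx <- qr(Xc)
  if (qrx$rank < k) {
    cols <- colnames(X) %||% paste0("x", seq_len(k))
    abort(sprintf("rank-deficient design: collinear columns among %s",
                  paste(cols, collapse = ", ")),
          class = "bayeswell_rank_error")
  }
  fit <- qr.fitted(qrx, yc)
  r2 <- sum(fit^2) / tss
  base + ((n - 1 - k) / 2) * log1p(g) -
    ((n - 1) / 2) * log1p(g * (1 - r2))
}

#' Enumerate admissible predictor subsets
#'
#' All subsets of the candidate list; when `hierarchy = TRUE` an interaction
#' term is admissible only in models that also contain both its parents.
#'
#' @param candidates Character vector of candidate names. Interactions are
#'   written `"a:b"`.
#' @param hierarchy Enforce strong heredity for interactions.
#' @param guard Maximum number of candidates (exact enumeration only).
#' @return A list of character vectors (the empty vector is the null model).
#' @export
#' @examples
#' enumerate_models(c("A", "B", "A:B")) # 5 admissible models
enumerate_models <- function(candidates, hierarchy = TRUE, guard = 20L) {
  p <- length(candidates)
  if (p > guard)
    abort(sprintf(
      "%d candidates exceeds the exact-enumeration guard (%d); reduce the candidate set",
      p, guard))
  if (anyDuplicated(candidates))
    abort("duplicate candidate names")
  models <- list(character(0))
  if (p == 0L) return(models)
  for (j in seq_len(p)) # binary expansion of the 2^p subsets
    models <- c(models, lapply(models, c, candidates[j]))
  if (hierarchy) {
    inter <- grep(":", candidates, fixed = TRUE, value = TRUE)
    if (length(inter)) {
      parents <- strsplit(inter, ":", fixed = TRUE)
      ok <- vapply(models, function(m) {
        sel <- inter %in% m
        all(vapply(which(sel), function(i)
          all(parents[[i]] %in% m), logical(1)))
      }, logical(1))
      models <- models[ok]
    }
  }
  models
}

# Build the column matrix for a set of terms; interactions "a:b" are the
# elementwise product of their parent columns.
candidate_columns <- function(data, terms) {
  if (!length(terms)) return(NULL)
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    missing <- setdiff(parts, names(data))
    if (length(missing))
      abort(sprintf("candidate `%s` needs missing column(s): %s", tm,
                    paste(missing, collapse = ", ")))
    Reduce(`*`, lapply(parts, function(v) as.numeric(data[[v]])))
  })
  matrix(unlist(cols), ncol = length(terms),
         dimnames = list(NULL, terms))
}

#' Bayesian Model Averaging over candidate predictors
#'
#' @param data Tibble containing the response and every parent column of the
#'   candidates (create indicator columns with `dplyr::mutate()` or via
#'   [bma_candidates()]). Rows with missing values in any used column are
#'   dropped.
#' @param response Response column name.
#' @param candidates Character vector of candidate predictors; interactions
#'   as `"a:b"`.
#' @param g Zellner g-prior scale (default: number of rows used).
#' @param hierarchy Enforce interaction heredity during enumeration.
#' @return A list of class `bma_result`: `inclusion` (tibble of per-candidate
#'   inclusion probabilities and model-averaged coefficient means/sds),
#'   `models` (tibble of all models with log marginals and posterior
#'   probabilities), `n`, `g`, `dropped` (models removed as rank-deficient).
#' @export
#' @examples
#' d <- tibble::tibble(y = rnorm(50), a = rnorm(50), b = rnorm(50))
#' bma_fit(d, "y", c("a", "b", "a:b"))
bma_fit <- function(data, response, candidates, g = NULL, hierarchy = TRUE) {
  data <- tibble::as_tibble(data)
  if (!response %in% names(data))
    abort(sprintf("unknown response `%s`", response))
  parents <- unique(unlist(strsplit(candidates, ":", fixed = TRUE)))
  missing <- setdiff(parents, names(data))
  if (length(missing))
    abort(sprintf("candidate parent column(s) missing: %s",
                  paste(missing, collapse = ", ")))
  used <- c(response, parents)
  data <- data[complete.cases(data[used]), , drop = FALSE]
  y <- as.numeric(data[[response]])
  n <- length(y)
  if (is.null(g)) g <- n
  Xall <- candidate_columns(data, candidates)

  models <- enumerate_models(candidates, hierarchy = hierarchy)
  logm <- numeric(length(models))
  cond <- vector("list", length(models))
  keep <- rep(TRUE, length(models))
  for (i in seq_along(models)) {
    sel <- candidates %in% models[[i]]
    Xm <- if (any(sel)) Xall[, sel, drop = FALSE] else NULL
    res <- tryCatch(
      list(lm = log_marginal(y, Xm, g = g),
           mom = conditional_moments(y, Xm, g = g)),
      bayeswell_rank_error = function(e) NULL)
    if (is.null(res)) { keep[i] <- FALSE; next }
    logm[i] <- res$lm
    cond[[i]] <- res$mom
  }
  if (!all(keep)) {
    warning(sprintf("dropped %d rank-deficient model(s); renormalising",
                    sum(!keep)), call. = FALSE)
    models <- models[keep]; logm <- logm[keep]; cond <- cond[keep]
  }
  w <- exp(logm - max(logm))
  post <- w / sum(w)

  # model-averaged moments: mean = sum_w m_j ; var = sum_w (v_j + m_j^2) - mean^2,
  # with m_j = v_j = 0 in models excluding the predictor
  inc <- mean_avg <- second <- setNames(numeric(length(candidates)),
                                        candidates)
  for (i in seq_along(models)) {
    sel <- models[[i]]
    if (!length(sel)) next
    inc[sel] <- inc[sel] + post[i]
    m <- cond[[i]]$mean; v <- cond[[i]]$var
    mean_avg[sel] <- mean_avg[sel] + post[i] * m
    second[sel] <- second[sel] + post[i] * (v + m^2)
  }
  model_tbl <- tibble::tibble(
    model = vapply(models, function(m)
      if (length(m)) paste(m, collapse = " + ") else "(null)", character(1)),
    size = lengths(models),
    log_marginal = logm,
    posterior_prob = post) |>
    dplyr::arrange(dplyr::desc(.data$posterior_prob))

  structure(list(
    inclusion = tibble::tibble(
      term = candidates,
      inclusion_prob = unname(inc),
      estimate = unname(mean_avg),
      std.error = sqrt(pmax(unname(second - mean_avg^2), 0))),
    models = model_tbl, n = n, g = g, response = response,
    dropped = sum(!keep)), class = "bma_result")
}

# Conditional posterior moments of the slopes within one model under the
# g-prior: beta | y, M ~ (shrunken OLS, multivariate t); mean g/(1+g) bhat,
# covariance g/(1+g) s2 (Xc'Xc)^-1 with s2 from the shrunken residual fit.
conditional_moments <- function(y, X, g) {
  if (is.null(X) || NCOL(X) == 0L)
    return(list(mean = numeric(0), var = numeric(0)))
  X <- as.matrix(X)
  n <- length(y); k <- ncol(X)
  yc <- y - mean(y)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  XtX <- crossprod(Xc)
  bhat <- solve(XtX, crossprod(Xc, yc))
  shrink <- g / (1 + g)
  tss <- sum(yc^2)
  r2 <- sum((Xc %*% bhat)^2) / tss
  # posterior scale: E[sigma^2 | y, M] under the reference prior
  s2 <- tss * (1 - shrink * r2) / (n - 3)
  vcov <- shrink * s2 * solve(XtX)
  list(mean = shrink * drop(bhat), var = diag(vcov))
}

#' @export
print.bma_result <- function(x, ...) {
  cat(sprintf("<bma_result> response %s, n = %d, g = %g, %d models\n",
              x$response, x$n, x$g, nrow(x$models)))
  print(x$inclusion)
  invisible(x)
}

#' @method tidy bma_result
#' @export
tidy.bma_result <- function(x, ...) x$inclusion

#' @method glance bma_result
#' @export
glance.bma_result <- function(x, ...) {
  tibble::tibble(nobs = x$n, n_models = nrow(x$models), g = x$g,
                 top_model = x$models$model[1],
                 top_prob = x$models$posterior_prob[1],
                 dropped = x$dropped)
}

#' Inclusion-probability bar chart for a BMA result
#'
#' @param object A `bma_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bma_result
#' @export
autoplot.bma_result <- function(object, ...) {
  dat <- dplyr::mutate(object$inclusion,
                       term = factor(.data$term,
                                     levels = .data$term[order(.data$inclusion_prob)]))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$inclusion_prob, y = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "posterior inclusion probability", y = NULL)
}

#' Derive BMA candidate columns from similarity clusters and thresholds
#'
#' Adds to `cohort`: one indicator per non-reference similarity cluster
#' (`cluster2`, `cluster3`, ...), one dichotomy per CART threshold
#' (`child_age_le8`, `maternal_age_le53`, `wessex_le8`, ...), and returns
#' the candidate list including cluster-by-dichotomy interactions.
#'
#' @param cohort Scored cohort tibble.
#' @param clusters Tibble from [group_by_similarity()].
#' @param thresholds Named list mapping covariate name to a numeric vector
#'   of thresholds (typically from [extract_thresholds()]).
#' @param interactions Add cluster x dichotomy interaction candidates.
#' @return A list with `data` (augmented cohort) and `candidates`.
#' @export
bma_candidates <- function(cohort, clusters, thresholds = list(),
                           interactions = TRUE) {
  cohort <- tibble::as_tibble(cohort)
  cl <- clusters$cluster[match(cohort$group, clusters$group)]
  cluster_terms <- character(0)
  for (k in setdiff(sort(unique(clusters$cluster)), 1L)) {
    nm <- paste0("cluster", k)
    cohort[[nm]] <- as.numeric(cl == k)
    cluster_terms <- c(cluster_terms, nm)
  }
  dich_terms <- character(0)
  for (v in names(thresholds)) {
    for (t in thresholds[[v]]) {
      nm <- paste0(v, "_le", gsub("[^0-9a-zA-Z]", "_", format(t)))
      cohort[[nm]] <- as.numeric(cohort[[v]] <= t)
      dich_terms <- c(dich_terms, nm)
    }
  }
  cands <- c(cluster_terms, dich_terms)
  if (interactions && length(cluster_terms) && length(dich_terms))
    cands <- c(cands, as.vector(outer(cluster_terms, dich_terms,
                                      paste, sep = ":")))
  list(data = cohort, candidates = cands)
}
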