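# Questionnaire scale scoring.
#
# Four scales are scored per dyad:
#   pgs    - Positive Gain Scale, 7 items, each 1-5, reverse coded so that
#            higher scores mean more positive gain; total 7-35.
#   pas5   - 5-item short Positive Affect Scale, items 1-5; total 5-25.
#   hads   - HADS depression subscale, 7 items, each 0-3; total 0-21
#            (scores above 7 indicate clinically significant depression).
#   stress - QRSF Parent and Family Problems subscale, 7 true/false items;
#            the score is the count of "true", 0-7.
# A scale with at least 75% of items answered is prorated (mean of answered
# items times the item count, rounded half up); below that it is left
# missing and the dyad is later dropped by apply_exclusions().

#' Score the four well-being scales
#'
#' @param items A `cohort_sim` object or its `items` tibble: one row per dyad
#'   with raw item columns `pgs_1..7` (original coding; reversed here),
#'   `pas5_1..5`, `hads_1..7` and logical `qrsf_1..7`.
#' @param min_completion Minimum answered fraction per scale below which the
#'   scale score is left missing (never zero).
#' @return A tibble with the non-item columns of the input plus, per scale,
#'   the score (`pgs`, `pas5`, `hads`, `stress`) and the answered fraction
#'   (`pgs_completion`, ...).
#' @export
#' @examples
#' sim <- generate_cohort(cohort_config(), seed = 1)
#' score_scales(sim$items)
score_scales <- function(items, min_completion = 0.75) {
  if (inherits(items, "cohort_sim")) items <- items$items
  items <- tibble::as_tibble(items)
  defs <- scale_defs()
  out <- dplyr::select(items, -dplyr::matches("^(pgs|pas5|hads|qrsf)_\\d+$"))
  for (m in measure_names()) {
    def <- defs[[m]]
    prefix <- if (m == "stress") "qrsf" else m
    cols <- paste0(prefix, "_", seq_len(def$items))
    missing_cols <- setdiff(cols, names(items))
    if (length(missing_cols))
      abort(sprintf("missing item columns for scale `%s`: %s", m,
                    paste(missing_cols, collapse = ", ")))
    mat <- as.matrix(dplyr::select(items, dplyr::all_of(cols)))
    mode(mat) <- "numeric"
    check_item_range(mat, def, m)
    if (def$reversed) mat <- (def$lo + def$hi) - mat
    answered <- rowSums(!is.na(mat))
    frac <- answered / def$items
    mean_ans <- rowMeans(mat, na.rm = TRUE)
    score <- round_half_up(mean_ans * def$items)
    score[frac < min_completion] <- NA_real_
    out[[m]] <- as.integer(score)
    out[[paste0(m, "_completion")]] <- frac
  }
  out
}

check_item_range <- function(mat, def, name) {
  vals <- mat[!is.na(mat)]
  if (length(vals) && (any(vals < def$lo) || any(vals > def$hi)))
    abort(sprintf("scale `%s` has item values outside [%d, %d]",
                  name, def$lo, def$hi))
  invisible(TRUE)
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' \eqn{\alpha = k/(k-1) \, (1 - \sum_j s_j^2 / s_T^2)} where \eqn{s_j^2} are
#' item variances and \eqn{s_T^2} the variance of the total score, computed on
#' complete rows. For dichotomous items this equals the Kuder-Richardson
#' (KR-20) coefficient.
#'
#' @param item_matrix Numeric (or logical) matrix/data frame, one column per
#'   item; rows with any missing item are dropped.
#' @return A single number in \eqn{(-\infty, 1]}.
#' @export
#' @examples
#' x <- rnorm(50)
#' cronbach_alpha(cbind(x + rnorm(50, sd = .3), x + rnorm(50, sd = .3)))
cronbach_alpha <- function(item_matrix) {
  mat <- as.matrix(item_matrix)
  mode(mat) <- "numeric"
  mat <- mat[complete.cases(mat), , drop = FALSE]
  k <- ncol(mat)
  if (k < 2L) abort("cronbach_alpha() needs at least 2 items")
  if (nrow(mat) < 2L) abort("cronbach_alpha() needs at least 2 complete rows")
  total_var <- var(rowSums(mat))
  if (total_var == 0)
    abort("Cronbach's alpha is undefined: total-score variance is zero",
          class = "bayeswell_degenerate_error")
  k / (k - 1) * (1 - sum(apply(mat, 2, var)) / total_var)
}
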