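# Regression trees for covariate dichotomisation.
#
# Binary recursive partitioning minimising within-node sum of squared
# deviations, with splits placed at observed covariate values ("x <= t"
# goes left). The trees are not used for prediction: their split thresholds
# define the binary indicator covariates (child age <= 8, maternal age
# <= 53, Wessex below maximum, ...) handed to the model-averaging stage,
# so the implementation favours coarse, deterministic, exactly-recoverable
# splits over predictive refinement. No pruning or cross-validation.

#' Regression-tree hyperparameters
#'
#' @param max_depth Maximum tree depth (root = depth 1).
#' @param min_leaf Minimum rows in any leaf.
#' @param min_improve Minimum split improvement as a fraction of the parent
#'   node's sum of squared deviations.
#' @return A list of class `tree_params`.
#' @export
tree_params <- function(max_depth = 3L, min_leaf = 20L, min_improve = 0.01) {
  if (max_depth < 1L) stop_bad_arg("max_depth", "must be >= 1")
  if (min_leaf < 1L) stop_bad_arg("min_leaf", "must be >= 1")
  if (min_improve < 0) stop_bad_arg("min_improve", "must be >= 0")
  structure(list(max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf),
                 min_improve = min_improve),
            class = "tree_params")
}

#' Fit a regression tree of a measure on cohort covariates
#'
#' @param cohort Scored cohort tibble.
#' @param measure Response column (`"pgs"`, `"pas5"`, `"hads"`, `"stress"`).
#' @param covariates Candidate split variables; `"wessex_max"` (indicator
#'   for self-help at maximum) is derived on the fly.
#' @param params A [tree_params()].
#' @param wessex_max Scale maximum used to derive `wessex_max`.
#' @return A nested list of class `well_tree`. Internal nodes carry `var`,
#'   `threshold` (values `<= threshold` go left), `mean`, `n`, `left`,
#'   `right`; leaves carry `mean` and `n`. Ties between equally good splits
#'   are broken by the smaller threshold, then by covariate order; the fit
#'   is invariant to row order.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' tree <- fit_tree(cohort, "stress")
#' extract_thresholds(tree, "child_age")
fit_tree <- function(cohort, measure,
                     covariates = c("wessex", "child_age", "maternal_age"),
                     params = tree_params(), wessex_max = 9L) {
  stopifnot(inherits(params, "tree_params"))
  cohort <- tibble::as_tibble(cohort)
  if (!measure %in% names(cohort))
    abort(sprintf("cohort lacks a `%s` column", measure))
  if ("wessex_max" %in% covariates)
    cohort$wessex_max <- as.numeric(cohort$wessex == wessex_max)
  bad <- setdiff(covariates, names(cohort))
  if (length(bad))
    abort(sprintf("unknown covariate(s): %s", paste(bad, collapse = ", ")))

  keep <- !is.na(cohort[[measure]])
  for (v in covariates) keep <- keep & !is.na(cohort[[v]])
  y <- as.numeric(cohort[[measure]][keep])
  Xc <- lapply(covariates, function(v) as.numeric(cohort[[v]][keep]))
  names(Xc) <- covariates
  if (length(y) < 2L * params$min_leaf)
    abort(sprintf("need at least %d rows with a non-missing `%s`",
                  2L * params$min_leaf, measure))

  node <- grow_node(y, Xc, depth = 1L, params = params)
  structure(node, class = "well_tree", measure = measure,
            covariates = covariates)
}

node_sse <- function(y) sum((y - mean(y))^2)

# Best split of one covariate: candidates are its observed unique values
# (excluding the maximum, which sends everything left). Returns NULL when
# no admissible split exists.
best_split_var <- function(y, x, min_leaf) {
  ord <- order(x, method = "radix")
  xs <- x[ord]; ys <- y[ord]
  n <- length(y)
  # prefix sums give left/right SSE at every cut in O(n)
  cs <- cumsum(ys); cs2 <- cumsum(ys^2)
  tot <- cs[n]; tot2 <- cs2[n]
  # candidate cut after position i (1..n-1), only at the last occurrence of
  # each distinct value so the threshold is an observed value
  last <- which(diff(xs) > 0)
  if (!length(last)) return(NULL)
  nl <- last
  ok <- nl >= min_leaf & (n - nl) >= min_leaf
  if (!any(ok)) return(NULL)
  nl <- nl[ok]
  sse <- (cs2[nl] - cs[nl]^2 / nl) +
    ((tot2 - cs2[nl]) - (tot - cs[nl])^2 / (n - nl))
  best <- which.min(sse) # which.min takes the first (smallest threshold) tie
  list(threshold = xs[nl[best]], sse = sse[best])
}

grow_node <- function(y, Xc, depth, params) {
  n <- length(y)
  leaf <- list(leaf = TRUE, mean = mean(y), n = n)
  parent_sse <- node_sse(y)
  if (depth >= params$max_depth || parent_sse == 0 ||
      n < 2L * params$min_leaf)
    return(leaf)

  best <- NULL
  for (v in names(Xc)) { # covariate order breaks exact ties across variables
    cand <- best_split_var(y, Xc[[v]], params$min_leaf)
    if (!is.null(cand) && (is.null(best) || cand$sse < best$sse))
      best <- c(cand, var = v)
  }
  if (is.null(best)) return(leaf)
  if ((parent_sse - best$sse) < params$min_improve * parent_sse) return(leaf)

  go_left <- Xc[[best$var]] <= best$threshold
  split_side <- function(side) grow_node(
    y[side], lapply(Xc, `[`, side), depth + 1L, params)
  list(leaf = FALSE, var = best$var, threshold = best$threshold,
       mean = mean(y), n = n,
       left = split_side(go_left), right = split_side(!go_left))
}

#' @export
print.well_tree <- function(x, ...) {
  cat(sprintf("<well_tree> response: %s\n", attr(x, "measure")))
  print_node <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (isTRUE(node$leaf)) {
      cat(sprintf("%s* mean %.3f (n = %d)\n", pad, node$mean, node$n))
    } else {
      cat(sprintf("%s%s <= %g (n = %d, mean %.3f)\n", pad, node$var,
                  node$threshold, node$n, node$mean))
      print_node(node$left, indent + 1L)
      print_node(node$right, indent + 1L)
    }
  }
  print_node(x, 0L)
  invisible(x)
}

#' Collect the split thresholds a tree uses for one variable
#'
#' These thresholds define the binary indicator features (e.g. child age
#' `<=`/`>` 8) offered to the model-averaging stage.
#'
#' @param tree A `well_tree`.
#' @param variable Covariate name.
#' @return Sorted, de-duplicated numeric vector (empty when the variable is
#'   never split on).
#' @export
extract_thresholds <- function(tree, variable) {
  stopifnot(inherits(tree, "well_tree"))
  walk <- function(node) {
    if (isTRUE(node$leaf)) return(numeric(0))
    c(if (node$var == variable) node$threshold,
      walk(node$left), walk(node$right))
  }
  sort(unique(walk(tree)))
}

#' Tabulate every split in a tree
#'
#' @param x A `well_tree`.
#' @param ... Unused.
#' @return A tibble with `variable`, `threshold`, `depth`, `n`.
#' @method tidy well_tree
#' @export
tidy.well_tree <- function(x, ...) {
  walk <- function(node, depth) {
    if (isTRUE(node$leaf)) return(NULL)
    dplyr::bind_rows(
      tibble::tibble(variable = node$var, threshold = node$threshold,
                     depth = depth, n = node$n),
      walk(node$left, depth + 1L), walk(node$right, depth + 1L))
  }
  out <- walk(x, 1L)
  if (is.null(out))
    out <- tibble::tibble(variable = character(), threshold = numeric(),
                          depth = integer(), n = integer())
  out
}

# Leaf-mean prediction (used by the tree invariants and tests).
predict_tree <- function(tree, newdata) {
  one <- function(node, row) {
    while (!isTRUE(node$leaf))
      node <- if (row[[node$var]] <= node$threshold) node$left else node$right
    node$mean
  }
  vapply(seq_len(nrow(newdata)), function(i) one(tree, newdata[i, ]),
         numeric(1))
}
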