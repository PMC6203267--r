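# Study exclusion rules, applied sequentially in the order the study
# reported them: (1) respondent is not the child's mother or adoptive
# mother; (2) child aged under 2 years; (3) fewer than 75% of items
# completed on an analysed scale; (4) SCQ total below the screening cut-off
# (applied wherever an SCQ total was collected, i.e. the autism reference
# group). Each excluded record is counted under the first rule that fires.

#' Apply the cohort exclusion rules
#'
#' @param records A scored tibble from [score_scales()]: must carry
#'   `respondent_role`, `child_age`, per-scale completion fractions and (for
#'   the reference group) `scq`.
#' @param scq_cutoff Records with a recorded SCQ total strictly below this
#'   value are excluded (default 15; a total of exactly 15 is retained).
#' @param min_completion Minimum answered fraction per analysed scale.
#' @param scales Scales whose completion is checked.
#' @return The retained tibble, with the per-rule exclusion counts attached
#'   as the `exclusions` attribute (see [exclusion_ledger()]).
#' @export
apply_exclusions <- function(records,
                             scq_cutoff = 15,
                             min_completion = 0.75,
                             scales = c("pgs", "pas5", "hads", "stress")) {
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  rules <- c("non_mother", "child_under_2", "incomplete_scales",
             "scq_below_cutoff")
  if (n == 0L) {
    ledger <- tibble::tibble(rule = rules, n_excluded = 0L)
    attr(records, "exclusions") <- ledger
    return(records)
  }

  role_ok <- !(records$respondent_role %in%
                 c("mother", "adoptive mother", "adoptive-mother"))
  fail_role <- role_ok
  fail_age <- records$child_age < 2

  comp_cols <- paste0(scales, "_completion")
  missing_cols <- setdiff(comp_cols, names(records))
  if (length(missing_cols))
    abort(paste("records lack completion columns:",
                paste(missing_cols, collapse = ", ")))
  comp <- as.matrix(records[comp_cols])
  fail_comp <- rowSums(comp < min_completion) > 0

  scq <- if ("scq" %in% names(records)) records$scq else rep(NA_real_, n)
  fail_scq <- !is.na(scq) & scq < scq_cutoff

  # first rule wins, in reporting order
  reason <- rep(NA_character_, n)
  reason[fail_scq] <- "scq_below_cutoff"
  reason[fail_comp] <- "incomplete_scales"
  reason[fail_age] <- "child_under_2"
  reason[fail_role] <- "non_mother"

  ledger <- tibble::tibble(
    rule = rules,
    n_excluded = vapply(rules, function(r) sum(reason == r, na.rm = TRUE),
                        integer(1), USE.NAMES = FALSE))
  retained <- records[is.na(reason), , drop = FALSE]
  attr(retained, "exclusions") <- ledger
  retained
}

#' Retrieve the exclusion ledger of a filtered cohort
#'
#' @param x A tibble returned by [apply_exclusions()].
#' @return A tibble with columns `rule` and `n_excluded`; counts sum to
#'   (input rows - retained rows).
#' @export
exclusion_ledger <- function(x) {
  ledger <- attr(x, "exclusions")
  if (is.null(ledger)) abort("no exclusion ledger attached; run apply_exclusions()")
  ledger
}
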