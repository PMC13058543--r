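# Score-outcome curves, dichotomisation and cutpoint selection.
#
# The published thresholds (high C-CTS at >= 5, high SA-CTS at >= 4) were
# identified visually from per-score percent-critical curves. The
# reproducible surrogate implemented here sweeps all candidate cutoffs,
# runs the exact 2x2 test at each, and selects the feasible cutoff with
# the smallest two-sided p (ties broken toward the smaller cutoff). The
# full sweep is always returned so users can apply their own judgement.

check_outcomes <- function(outcomes) {
  bad <- setdiff(unique(outcomes), c("critical", "non_critical"))
  if (length(bad) > 0 || anyNA(outcomes)) {
    stop("outcomes must be 'critical' or 'non_critical'")
  }
  invisible(outcomes)
}

#' Per-score outcome curve
#'
#' Counts of critical and non-critical patients and the critical fraction
#' at every score value. Unattained values inside `score_range` are
#' reported with zero counts and `NaN` fraction.
#'
#' @param scores Integer vector of per-patient score totals.
#' @param outcomes Character vector (`"critical"` / `"non_critical"`) of
#'   the same length.
#' @param score_range Optional `c(min, max)`; defaults to the attained
#'   range. Use [scheme_range()] to report a scheme's full range.
#' @return A data.frame with `score`, `n_critical`, `n_non_critical`,
#'   `n`, `fraction_critical`.
#' @export
score_outcome_curve <- function(scores, outcomes, score_range = NULL) {
  if (length(scores) != length(outcomes)) {
    stop("scores and outcomes must have equal length")
  }
  if (length(scores) < 1) stop("need at least one patient")
  check_outcomes(outcomes)
  if (is.null(score_range)) score_range <- range(scores)
  values <- seq(score_range[1], score_range[2])
  crit <- vapply(values, function(v) sum(scores == v & outcomes == "critical"),
                 numeric(1))
  noncrit <- vapply(values,
                    function(v) sum(scores == v & outcomes == "non_critical"),
                    numeric(1))
  data.frame(score = values,
             n_critical = as.integer(crit),
             n_non_critical = as.integer(noncrit),
             n = as.integer(crit + noncrit),
             fraction_critical = crit / (crit + noncrit))
}

#' Dichotomise scores at a cutoff against outcome
#'
#' @inheritParams score_outcome_curve
#' @param cutoff Integer threshold: the high group is `score >= cutoff`.
#' @return A 2x2 matrix with rows `(low, high)` and columns
#'   `(non_critical, critical)`.
#' @examples
#' dichotomize(c(2, 3, 5, 7), 5, c("non_critical", "critical",
#'                                 "critical", "critical"))
#' @export
dichotomize <- function(scores, cutoff, outcomes) {
  if (length(scores) != length(outcomes)) {
    stop("scores and outcomes must have equal length")
  }
  check_outcomes(outcomes)
  high <- scores >= cutoff
  tab <- matrix(c(sum(!high & outcomes == "non_critical"),
                  sum(!high & outcomes == "critical"),
                  sum(high & outcomes == "non_critical"),
                  sum(high & outcomes == "critical")),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("low", "high"),
                                outcome = c("non_critical", "critical")))
  tab
}

#' Sweep candidate cutoffs and select a threshold
#'
#' Dichotomises the score at every candidate cutoff, runs the exact 2x2
#' test on each feasible split (both groups non-empty), and selects the
#' cutoff with the minimum two-sided p, breaking ties toward the smallest
#' cutoff. Sensitivity is the fraction of critical patients at or above
#' the cutoff; specificity the fraction of non-critical patients below it.
#'
#' @inheritParams score_outcome_curve
#' @param candidate_cutoffs Integer vector of at least two candidates.
#' @param conf_level Confidence level for the per-cutoff exact CI.
#' @param with_estimates If `FALSE`, skip the odds-ratio and CI
#'   computation (p-values only); useful in large replicate experiments.
#' @return An object of class `cutpoint_sweep`: a list with `sweep` (one
#'   row per candidate: counts, `p`, `or`, `ci_low`, `ci_high`,
#'   `sensitivity`, `specificity`, `feasible`), `selected_cutoff` and
#'   `selection_rule`.
#' @export
cutpoint_sweep <- function(scores, outcomes, candidate_cutoffs,
                           conf_level = 0.95, with_estimates = TRUE) {
  if (length(candidate_cutoffs) < 2) stop("need at least two candidates")
  check_outcomes(outcomes)
  candidate_cutoffs <- sort(unique(as.integer(candidate_cutoffs)))
  n_crit <- sum(outcomes == "critical")
  n_noncrit <- sum(outcomes == "non_critical")
  rows <- lapply(candidate_cutoffs, function(cc) {
    tab <- dichotomize(scores, cc, outcomes)
    feasible <- all(rowSums(tab) > 0)
    p <- or <- lo <- hi <- NA_real_
    if (feasible) {
      p <- fisher_2x2(tab)
      if (with_estimates) {
        or <- cmle_odds_ratio(tab)
        ci <- exact_or_ci(tab, conf_level)
        lo <- ci[1]; hi <- ci[2]
      }
    }
    data.frame(cutoff = cc,
               n_low = sum(tab["low", ]), n_high = sum(tab["high", ]),
               low_non_critical = tab["low", "non_critical"],
               low_critical = tab["low", "critical"],
               high_non_critical = tab["high", "non_critical"],
               high_critical = tab["high", "critical"],
               feasible = feasible, p = p, or = or,
               ci_low = unname(lo), ci_high = unname(hi),
               sensitivity = if (n_crit > 0)
                 tab["high", "critical"] / n_crit else NA_real_,
               specificity = if (n_noncrit > 0)
                 tab["low", "non_critical"] / n_noncrit else NA_real_)
  })
  sweep <- do.call(rbind, rows)
  rownames(sweep) <- NULL
  if (!any(sweep$feasible)) stop("no feasible candidate cutoff")
  ok <- sweep[sweep$feasible, ]
  selected <- ok$cutoff[which.min(ok$p)]  # which.min takes the first = smallest
  structure(list(sweep = sweep,
                 selected_cutoff = as.integer(selected),
                 selection_rule = "min_p_smallest_cutoff",
                 conf_level = conf_level),
            class = "cutpoint_sweep")
}

#' @export
print.cutpoint_sweep <- function(x, ...) {
  cat("Cutpoint sweep (", nrow(x$sweep), " candidates, rule ",
      x$selection_rule, ")\n", sep = "")
  cat("Selected cutoff: score >=", x$selected_cutoff, "\n")
  print(x$sweep, digits = 4)
  invisible(x)
}
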