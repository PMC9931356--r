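#' Branch test performance: sensitivity, specificity, likelihood ratios
#'
#' @param sensitivity,specificity Proportions strictly inside (0, 1).
#' @return A `branch_performance` object with `lr_pos = sens / (1 - spec)`
#'   and `lr_neg = (1 - sens) / spec`.
#' @export
branch_perf <- function(sensitivity, specificity) {
  stopifnot(sensitivity > 0, sensitivity < 1, specificity > 0, specificity < 1)
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 lr_pos = sensitivity / (1 - specificity),
                 lr_neg = (1 - sensitivity) / specificity),
            class = "branch_performance")
}

#' Post-test probability from pre-test probability and likelihood ratio
#'
#' Odds form of Bayes' theorem: post-test odds = pre-test odds x LR, with
#' odds = p / (1 - p). The pre-test probability is the disease prevalence in
#' the presenting population (possibly comorbidity-adjusted upward).
#'
#' @param pretest Pre-test probability, strictly inside (0, 1).
#' @param lr Likelihood ratio of the observed test result, > 0.
#' @return Post-test probability in (0, 1).
#' @examples
#' post_test_probability(0.5, 1)  # uninformative test: 0.5
#' post_test_probability(0.1, 9)  # 0.5
#' @export
post_test_probability <- function(pretest, lr) {
  stopifnot(all(pretest > 0 & pretest < 1), all(lr > 0))
  odds <- pretest / (1 - pretest) * lr
  odds / (1 + odds)
}

#' Likelihood ratio required to reach a target post-test probability
#'
#' Inverse of [post_test_probability()]: `lr = target_odds / pretest_odds`.
#' Strictly decreasing in the pre-test probability — a condition of lower
#' prevalence requires a higher likelihood ratio to reach the same post-test
#' probability, which is why high-specificity tests (e.g. a CRP branch) are
#' most valuable where prevalence is low.
#'
#' @param pretest,target_posttest Probabilities strictly inside (0, 1).
#' @return The required likelihood ratio.
#' @examples
#' required_lr(0.05, 0.5)  # 19
#' required_lr(0.2, 0.5)   # 4
#' @export
required_lr <- function(pretest, target_posttest) {
  stopifnot(all(pretest > 0 & pretest < 1),
            all(target_posttest > 0 & target_posttest < 1))
  (target_posttest / (1 - target_posttest)) / (pretest / (1 - pretest))
}

#' Build an ROC grid for a continuous test
#'
#' @param cutoff Strictly increasing cutoff values.
#' @param sensitivity Non-increasing along increasing cutoff.
#' @param specificity Non-decreasing along increasing cutoff.
#' @return A `roc_grid` data frame.
#' @export
roc_grid <- function(cutoff, sensitivity, specificity) {
  stopifnot(length(cutoff) == length(sensitivity),
            length(cutoff) == length(specificity))
  if (is.unsorted(cutoff, strictly = TRUE))
    stopf("cutoffs must be strictly increasing")
  if (any(diff(sensitivity) > 1e-12))
    stopf("sensitivity must be non-increasing along increasing cutoff")
  if (any(diff(specificity) < -1e-12))
    stopf("specificity must be non-decreasing along increasing cutoff")
  stopifnot(all(sensitivity > 0 & sensitivity < 1),
            all(specificity > 0 & specificity < 1))
  structure(data.frame(cutoff = cutoff, sensitivity = sensitivity,
                       specificity = specificity),
            class = c("roc_grid", "data.frame"))
}

#' Choose the lowest test cutoff reaching a target post-test probability
#'
#' Scans the ROC grid from the lowest cutoff upward and returns the first
#' whose positive likelihood ratio achieves a post-test probability at or
#' above the target. When the pre-test probability rises (e.g. a child with
#' comorbidities), a lower cutoff suffices for the same target — the chosen
#' cutoff is non-increasing in the pre-test probability. If no cutoff
#' reaches the target, the best achievable cutoff is returned and flagged.
#'
#' @param grid A [roc_grid()].
#' @param pretest Pre-test probability in (0, 1).
#' @param target_posttest Target post-test probability in (0, 1).
#' @return List: `cutoff`, `posttest` (achieved), `lr_pos`,
#'   `achieved_target` (logical).
#' @export
choose_cutoff <- function(grid, pretest, target_posttest) {
  stopifnot(pretest > 0, pretest < 1,
            target_posttest > 0, target_posttest < 1)
  lr <- grid$sensitivity / (1 - grid$specificity)
  post <- post_test_probability(pretest, lr)
  ok <- which(post >= target_posttest)
  if (length(ok)) {
    i <- ok[1L]
    list(cutoff = grid$cutoff[i], posttest = post[i], lr_pos = lr[i],
         achieved_target = TRUE)
  } else {
    i <- which.max(post) # ties: lowest cutoff
    list(cutoff = grid$cutoff[i], posttest = post[i], lr_pos = lr[i],
         achieved_target = FALSE)
  }
}

#' Wilson score confidence interval for a proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level.
#' @return Numeric `c(lower, upper)`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Empirical performance of an algorithm branch on labelled cases
#'
#' Replays each labelled case through the consultation engine and counts the
#' 2x2 table of "diagnosis proposed" (pre-review: the algorithm is measured,
#' not the clinician) against the gold condition label. Returns sensitivity,
#' specificity and likelihood ratios with 95% Wilson score intervals; a zero
#' cell makes the corresponding LR undefined and it is reported as `NA`,
#' never fabricated.
#'
#' @param alg A validated `clinical_algorithm`.
#' @param diagnosis_id The diagnosis (branch) under evaluation.
#' @param cases List of patient cases from [generate_cases()] (or the same
#'   shape), each with a gold `label`.
#' @param positive_labels Gold labels counted as disease-positive for this
#'   branch.
#' @return List with `counts` (tp, fp, fn, tn), `sensitivity`,
#'   `specificity`, their `*_ci` Wilson intervals, `lr_pos`, `lr_neg`, `n`.
#' @export
branch_performance <- function(alg, diagnosis_id, cases, positive_labels) {
  if (!diagnosis_id %in% names(alg$diagnoses))
    stopf("unknown diagnosis '%s'", diagnosis_id)
  tp <- fp <- fn <- tn <- 0L
  for (cs in cases) {
    st <- replay_case(alg, cs)
    proposed <- diagnosis_id %in% names(st$proposals)
    positive <- cs$label %in% positive_labels
    if (proposed && positive) tp <- tp + 1L
    else if (proposed && !positive) fp <- fp + 1L
    else if (!proposed && positive) fn <- fn + 1L
    else tn <- tn + 1L
  }
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  spec <- if (fp + tn > 0L) tn / (fp + tn) else NA_real_
  lr_pos <- if (!is.na(sens) && !is.na(spec) && spec < 1) sens / (1 - spec)
            else NA_real_
  lr_neg <- if (!is.na(sens) && !is.na(spec) && spec > 0) (1 - sens) / spec
            else NA_real_
  list(counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
       sensitivity = sens,
       sensitivity_ci = wilson_interval(tp, tp + fn),
       specificity = spec,
       specificity_ci = wilson_interval(tn, fp + tn),
       lr_pos = lr_pos, lr_neg = lr_neg,
       n = length(cases))
}
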