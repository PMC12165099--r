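#' Evaluation metrics
#'
#' The quantitative layer used to evaluate judge performance and whole runs:
#' confusion-matrix metrics, F1 from precision/recall, rank-based AUROC,
#' half-up percentage success rates, subsample bootstrap of pass rates, and
#' research-efficiency accounting in sub-questions per person-day. Undefined
#' metrics (zero denominators) are reported as `NA` markers, never raised as
#' errors, so batch evaluation never aborts.
#'
#' @name evaluation-metrics
NULL

#' Confusion counts
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts)))
    adra_abort("domain", "counts must be non-negative integers")
  if (sum(counts) == 0) adra_abort("domain", "total count must be positive")
  structure(as.list(counts), class = "confusion_counts")
}

#' Count a confusion matrix from predicted and true labels
#' @param predicted,truth logical vectors (positive = TRUE).
#' @return a [confusion_counts()].
#' @export
count_confusion <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  confusion_counts(sum(predicted & truth), sum(predicted & !truth),
                   sum(!predicted & !truth), sum(!predicted & truth))
}

#' Precision, recall, specificity and F1 from counts
#'
#' precision = tp/(tp+fp), recall = tp/(tp+fn), specificity = tn/(tn+fp),
#' F1 = harmonic mean of precision and recall. A zero denominator yields
#' `NA` for that metric.
#'
#' @param counts a [confusion_counts()].
#' @return named list of `precision`, `recall`, `specificity`, `f1`.
#' @export
confusion_metrics <- function(counts) {
  div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- div(counts$tp, counts$tp + counts$fp)
  recall <- div(counts$tp, counts$tp + counts$fn)
  list(precision = precision,
       recall = recall,
       specificity = div(counts$tn, counts$tn + counts$fp),
       f1 = f1_from_pr(precision, recall))
}

#' F1 score from precision and recall
#' @param precision,recall values in \[0,1\]; `NA` or a 0/0 pair yields `NA`.
#' @return harmonic mean `2*p*r/(p+r)`.
#' @export
f1_from_pr <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (any(c(precision, recall) < 0) || any(c(precision, recall) > 1))
    adra_abort("domain", "precision and recall must lie in [0,1]")
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with ties counted half: the probability
#' that a random positive scores above a random negative, plus half the
#' probability of a tie. Single-class input yields `NA`.
#'
#' @param confidence numeric scores, higher = more positive.
#' @param truth logical (or 0/1) true labels.
#' @return AUROC in \[0,1\], or `NA`.
#' @export
auroc <- function(confidence, truth) {
  truth <- as.logical(truth)
  stopifnot(length(confidence) == length(truth))
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(confidence, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Success rate as an integer percent
#' @param outcomes logical vector (or character of "success"/"fail").
#' @return `100 * successes / total`, rounded half-up (7 of 8 gives 88).
#' @export
success_rate <- function(outcomes) {
  if (length(outcomes) == 0) adra_abort("domain", "no outcomes")
  if (is.character(outcomes)) outcomes <- outcomes == "success"
  as.integer(round_half_up(100 * mean(outcomes)))
}

#' Subsample bootstrap of a pass rate
#'
#' Each replicate draws `floor(fraction * n)` outcomes without replacement
#' and records its pass rate — per-replicate subsampling, not the classical
#' with-replacement bootstrap. Deterministic under `seed`.
#'
#' @param outcomes logical vector (pass = TRUE) or character
#'   "pass"/"fail".
#' @param fraction resample fraction in (0, 1\]; default 0.8.
#' @param n_replicates number of replicates.
#' @param seed integer seed.
#' @return object of class `pass_rate_distribution`: `replicate_rates`,
#'   `fraction`, `n_replicates`.
#' @export
bootstrap_pass_rate <- function(outcomes, fraction = 0.8,
                                n_replicates = 1000L, seed = 1L) {
  if (is.character(outcomes)) outcomes <- outcomes == "pass"
  n <- length(outcomes)
  if (fraction <= 0 || fraction > 1)
    adra_abort("domain", "fraction must lie in (0, 1]")
  m <- floor(fraction * n)
  if (m < 1) adra_abort("domain", "fraction * n must be at least 1")
  rates <- with_seed(seed, vapply(seq_len(n_replicates), function(i)
    mean(outcomes[sample.int(n, m)]), numeric(1)))
  structure(list(replicate_rates = rates, fraction = fraction,
                 n_replicates = as.integer(n_replicates)),
            class = "pass_rate_distribution")
}

#' Research efficiency in sub-questions per person-day
#'
#' @param total_subq sub-questions solved in the window.
#' @param window_days window length in days.
#' @param team_size people attributable to the system's output.
#' @return `total_subq / window_days / team_size`.
#' @export
efficiency <- function(total_subq, window_days, team_size) {
  if (total_subq <= 0 || window_days <= 0 || team_size <= 0)
    adra_abort("domain", "all inputs must be positive")
  total_subq / window_days / team_size
}

#' Efficiency multiple of one rate over another
#' @param rate_a numerator rate (e.g. the system's).
#' @param rate_b positive reference rate (e.g. a human baseline).
#' @return `round(rate_a / rate_b)`, half-up, as integer.
#' @export
efficiency_multiple <- function(rate_a, rate_b) {
  if (rate_b <= 0) adra_abort("domain", "reference rate must be positive")
  as.integer(round_half_up(rate_a / rate_b))
}
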