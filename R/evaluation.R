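# Confusion-based measures, ROC/AUC, accuracy-coverage curves,
# enrichment-by-threshold analysis, delta-delta-G labeling and box-plot
# statistics. Positive class throughout: "change".

#' Confusion counts at a probability threshold
#'
#' An instance is predicted "change" iff its probability strictly exceeds
#' the threshold (so exactly 0.5 predicts "neutral" at the default).
#'
#' @param probs Predicted probabilities of structural change.
#' @param labels Binary truth (see [train_logreg()] label conventions).
#' @param threshold Decision threshold (default 0.5).
#' @return List with integer fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(probs, labels, threshold = 0.5) {
  if (length(probs) == 0L) stop("empty input")
  y <- as_binary01(labels)
  stopifnot(length(probs) == length(y))
  pred <- probs > threshold
  list(tp = sum(pred & y == 1), fp = sum(pred & y == 0),
       tn = sum(!pred & y == 0), fn = sum(!pred & y == 1))
}

#' Q2 and per-class accuracy/coverage
#'
#' `q2 = (TP+TN)/all`; `acc_change = TP/(TP+FP)`, `cov_change = TP/(TP+FN)`,
#' `acc_neutral = TN/(TN+FN)`, `cov_neutral = TN/(TN+FP)`. A metric with a
#' zero denominator is `NA`.
#'
#' @param counts Confusion counts from [confusion()].
#' @return Named list of the five metrics.
#' @export
class_metrics <- function(counts) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, list(
    q2 = ratio(tp + tn, tp + fp + tn + fn),
    acc_change = ratio(tp, tp + fp),
    cov_change = ratio(tp, tp + fn),
    acc_neutral = ratio(tn, tn + fn),
    cov_neutral = ratio(tn, tn + fp)
  ))
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold (equal scores grouped), giving
#' a ROC that starts at (0, 0) and ends at (1, 1); AUC by the trapezoid
#' rule, which under tie-grouping equals the Mann-Whitney statistic with
#' ties counted 1/2.
#'
#' @param probs Scores (higher means more likely "change").
#' @param labels Binary truth; both classes must be present.
#' @return List with `roc` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(probs, labels) {
  y <- as_binary01(labels)
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  ord <- order(probs, decreasing = TRUE)
  ys <- y[ord]; ps <- probs[ord]
  grp_last <- c(ps[-length(ps)] != ps[-1L], TRUE)  # last index of each tie group
  ctp <- cumsum(ys)[grp_last]
  cfp <- cumsum(1 - ys)[grp_last]
  tpr <- c(0, ctp / np)
  fpr <- c(0, cfp / nn)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Full evaluation report
#'
#' Confusion counts and class metrics at the given threshold, plus the ROC
#' curve and AUC.
#'
#' @inheritParams confusion
#' @return List: `threshold`, `counts`, `tpr`, `fpr`, the [class_metrics()]
#'   fields, `roc`, `auc`.
#' @export
eval_report <- function(probs, labels, threshold = 0.5) {
  cts <- confusion(probs, labels, threshold)
  cm <- class_metrics(cts)
  ra <- roc_auc(probs, labels)
  c(list(threshold = threshold, counts = cts,
         tpr = if ((cts$tp + cts$fn) > 0) cts$tp / (cts$tp + cts$fn) else NA_real_,
         fpr = if ((cts$fp + cts$tn) > 0) cts$fp / (cts$fp + cts$tn) else NA_real_),
    cm, list(roc = ra$roc, auc = ra$auc))
}

#' Accuracy-coverage pairs over a threshold grid
#'
#' For each threshold the per-class accuracy and coverage are computed,
#' sampling the accuracy-vs-coverage space for both classes.
#'
#' @inheritParams confusion
#' @param thresholds Probability grid (default `seq(0, 1, 0.05)`).
#' @return data.frame with columns `threshold`, `class`, `coverage`,
#'   `accuracy`, sorted by coverage within class.
#' @export
accuracy_coverage_curve <- function(probs, labels,
                                    thresholds = seq(0, 1, by = 0.05)) {
  rows <- do.call(rbind, lapply(thresholds, function(t) {
    cm <- class_metrics(confusion(probs, labels, t))
    data.frame(threshold = t, class = c("change", "neutral"),
               coverage = c(cm$cov_change, cm$cov_neutral),
               accuracy = c(cm$acc_change, cm$acc_neutral),
               stringsAsFactors = FALSE)
  }))
  rows[order(rows$class, rows$coverage), ]
}

#' Enrichment of observed effect among predicted-change mutants
#'
#' For each threshold `t`, the fraction of instances with an observed effect
#' among those predicted to change structure with probability `> t`. `NA`
#' when nothing is predicted above `t`.
#'
#' @param probs Predicted structural-change probabilities.
#' @param effect Binary external labels (effect / no effect), logical or
#'   0/1.
#' @param thresholds Default `seq(0.5, 0.9, 0.1)`, from uncertain to very
#'   strong predictions.
#' @return data.frame with `threshold`, `n_predicted`, `enrichment`.
#' @export
enrichment_curve <- function(probs, effect,
                             thresholds = seq(0.5, 0.9, by = 0.1)) {
  eff <- as.numeric(effect)
  stopifnot(length(probs) == length(eff), all(eff %in% c(0, 1)))
  do.call(rbind, lapply(thresholds, function(t) {
    sel <- probs > t
    data.frame(threshold = t, n_predicted = sum(sel),
               enrichment = if (any(sel)) mean(eff[sel]) else NA_real_)
  }))
}

#' Stability-effect label from a folding free energy change
#'
#' Mutations with `ddG < -1` or `ddG > 1` kcal/mol (strict) are labeled
#' "effect" (both stabilizing and destabilizing count); all others are
#' "neutral".
#'
#' @param ddg Delta-delta-G values in kcal/mol (vectorized).
#' @return Character vector over `{"effect", "neutral"}`.
#' @export
ddg_label <- function(ddg) {
  stopifnot(all(is.finite(ddg)))
  ifelse(ddg < -1 | ddg > 1, "effect", "neutral")
}

#' Box plot statistics
#'
#' First/third quartile and median by the linear-interpolation convention
#' (R quantile type 7); whiskers reach the most extreme data points no more
#' than 1.5 interquartile ranges beyond the box edges.
#'
#' @param values Numeric vector with at least one value.
#' @return List: `q1`, `median`, `q3`, `whisker_low`, `whisker_high`.
#' @export
box_stats <- function(values) {
  if (length(values) == 0L) stop("empty input")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- values[values >= q[1] - 1.5 * iqr]
  hi <- values[values <= q[3] + 1.5 * iqr]
  list(q1 = q[1], median = q[2], q3 = q[3],
       whisker_low = min(lo), whisker_high = max(hi))
}
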