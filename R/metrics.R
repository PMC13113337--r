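# Evaluation metrics for binary fetal-status classification.  Abnormal
# segments are the positive class throughout.

#' Confusion counts
#'
#' @param y_true,y_pred binary vectors (1 = abnormal = positive class).
#' @return list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort_input("length mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    abort_input("labels and predictions must be binary 0/1")
  }
  list(tp = sum(y_true == 1 & y_pred == 1),
       fp = sum(y_true == 0 & y_pred == 1),
       tn = sum(y_true == 0 & y_pred == 0),
       fn = sum(y_true == 1 & y_pred == 0))
}

#' Threshold metrics from confusion counts
#'
#' Accuracy, sensitivity (recall of the abnormal class), specificity, quality
#' index `QI = sqrt(SEN * SPE)` (geometric mean), F1 = `2TP / (2TP + FP + FN)`
#' and the Matthews correlation coefficient.  Zero denominators yield 0
#' (SEN/SPE/F1) and an MCC of 0 when any confusion-matrix marginal is empty.
#'
#' @param c confusion counts from [confusion()].
#' @return named list `acc`, `sen`, `spe`, `qi`, `f1`, `mcc`.
#' @export
classification_metrics <- function(c) {
  total <- c$tp + c$fp + c$tn + c$fn
  if (total <= 0) abort_input("empty confusion counts")
  safe_div <- function(num, den) if (den > 0) num / den else 0
  sen <- safe_div(c$tp, c$tp + c$fn)
  spe <- safe_div(c$tn, c$tn + c$fp)
  mcc_den <- sqrt(prod(c(c$tp + c$fp, c$tp + c$fn, c$tn + c$fp, c$tn + c$fn)))
  mcc <- if (mcc_den > 0) (c$tp * c$tn - c$fp * c$fn) / mcc_den else 0
  list(acc = (c$tp + c$tn) / total,
       sen = sen, spe = spe, qi = sqrt(sen * spe),
       f1 = safe_div(2 * c$tp, 2 * c$tp + c$fp + c$fn),
       mcc = mcc)
}

auc_rank <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

auc_trapezoid <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores so ties contribute a half-step trapezoid
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)[!duplicated(grp, fromLast = TRUE)]
  fp <- cumsum(1 - y)[!duplicated(grp, fromLast = TRUE)]
  tpr <- c(0, tp / sum(labels == 1))
  fpr <- c(0, fp / sum(labels == 0))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the ROC curve
#'
#' Computed twice -- as the trapezoidal area under the threshold-swept ROC
#' curve (tied scores grouped, contributing half steps) and as the
#' tie-corrected Mann-Whitney rank statistic -- and cross-checked; the two are
#' mathematically identical.
#'
#' @param scores abnormal-class probabilities (or any monotone score).
#' @param labels binary labels.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) abort_input("length mismatch")
  if (length(unique(labels)) < 2) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  a1 <- auc_trapezoid(scores, labels)
  a2 <- auc_rank(scores, labels)
  if (abs(a1 - a2) > 1e-10) {
    stop(sprintf("internal AUC cross-check failed (%.12f vs %.12f)", a1, a2))
  }
  a1
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; lower is better calibrated.
#' @param probs predicted probabilities in [0, 1].
#' @param outcomes binary outcomes.
#' @export
brier <- function(probs, outcomes) {
  if (length(probs) != length(outcomes)) abort_input("length mismatch")
  if (any(probs < 0 | probs > 1)) abort_input("probabilities must lie in [0, 1]")
  mean((probs - outcomes)^2)
}

#' Full metric set for one evaluation
#'
#' @param y_true binary labels.
#' @param probs abnormal-class probabilities.
#' @param threshold decision threshold for the confusion-based metrics.
#' @return named list `acc, sen, spe, qi, f1, mcc, auc, bs` plus the counts.
#' @export
metric_set <- function(y_true, probs, threshold = 0.5) {
  cc <- confusion(y_true, as.integer(probs >= threshold))
  m <- classification_metrics(cc)
  m$auc <- roc_auc(probs, y_true)
  m$bs <- brier(probs, y_true)
  m$counts <- cc
  m
}

#' Aggregate metric sets over repeated runs
#'
#' @param runs list of metric sets (named numeric entries).
#' @return list with per-metric `mean` and sample (`n-1`) `sd` (0 for a single
#'   run).
#' @export
aggregate_runs <- function(runs) {
  if (length(runs) == 0L) abort_input("no runs to aggregate")
  keys <- c("acc", "sen", "spe", "qi", "f1", "mcc", "auc", "bs")
  keys <- keys[keys %in% names(runs[[1]])]
  vals <- vapply(keys, function(k) {
    vapply(runs, function(r) as.numeric(r[[k]]), numeric(1))
  }, numeric(length(runs)))
  vals <- matrix(vals, nrow = length(runs), dimnames = list(NULL, keys))
  list(mean = colMeans(vals),
       sd = apply(vals, 2L, function(v) if (length(v) > 1) stats::sd(v) else 0))
}
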