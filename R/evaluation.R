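#' Detection and false-alarm rates from a confusion matrix
#'
#' Abnormal is the positive class: the detection rate is `TP / (TP + FN)`
#' (correctly flagged abnormal activities among all abnormal ones) and the
#' false alarm rate is `FP / (FP + TN)` (normal activities flagged abnormal
#' among all normal ones).
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return Named list with `detection_rate` and `false_alarm_rate`.
#' @export
rates <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  if (tp + fn == 0) stop("no abnormal samples: detection rate undefined")
  if (fp + tn == 0) stop("no normal samples: false alarm rate undefined")
  list(detection_rate = tp / (tp + fn),
       false_alarm_rate = fp / (fp + tn))
}

#' ROC curve and AUC for anomaly scores
#'
#' Sweeps a threshold over all distinct score values (equal scores grouped
#' into one step), producing the (false alarm rate, detection rate) curve
#' from (0, 0) to (1, 1), and integrates it by the trapezoid rule. This AUC
#' equals the tie-corrected Mann-Whitney statistic and is invariant under
#' strictly monotone score transforms.
#'
#' @param scores Numeric scores.
#' @param labels Logical or 0/1 vector, `TRUE`/1 = abnormal (positive).
#' @param higher_is_abnormal Orientation of `scores`; the package's model
#'   scores ([decision_score()], [onehmm_baseline()]) are "higher = more
#'   normal", so the default is `FALSE`.
#' @return Object of class `roc_result`: `points` (data frame with
#'   `false_alarm_rate`, `detection_rate`, `threshold`) and `auc`.
#' @export
roc_auc <- function(scores, labels, higher_is_abnormal = FALSE) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  s <- if (higher_is_abnormal) scores else -scores  # larger => more abnormal
  o <- order(s, decreasing = TRUE)
  s <- s[o]; lab <- labels[o]
  grp_end <- cumsum(rle(s)$lengths)                 # tie groups
  tp <- cumsum(lab)[grp_end]
  fp <- cumsum(!lab)[grp_end]
  dr <- c(0, tp / n_pos, 1)
  far <- c(0, fp / n_neg, 1)
  thr <- c(Inf, s[grp_end], -Inf)
  auc <- sum(diff(far) * (utils::head(dr, -1) + utils::tail(dr, -1)) / 2)
  structure(list(points = data.frame(false_alarm_rate = far,
                                     detection_rate = dr,
                                     threshold = thr),
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f over %d thresholds\n",
              x$auc, nrow(x$points) - 2))
  invisible(x)
}

#' Confusion matrix at an operating threshold
#'
#' @param scores,labels,higher_is_abnormal As in [roc_auc()].
#' @param threshold Samples whose oriented abnormality score exceeds this
#'   are predicted abnormal.
#' @return Named list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_at <- function(scores, labels, threshold,
                         higher_is_abnormal = FALSE) {
  labels <- as.logical(labels)
  s <- if (higher_is_abnormal) scores else -scores
  pred <- s > threshold
  list(tp = sum(pred & labels), fp = sum(pred & !labels),
       fn = sum(!pred & labels), tn = sum(!pred & !labels))
}
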