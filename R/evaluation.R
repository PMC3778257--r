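#' Confusion matrix and derived statistics from decision values
#'
#' Thresholds the decision values (strictly greater than `threshold` is
#' predicted favorable, anything else non-favorable) against the actual
#' labels and derives the usual screening statistics. Balanced accuracy here
#' is the sample version `(sensitivity + specificity) / 2`; its posterior
#' credible interval comes from [balanced_posterior_interval()].
#'
#' @param actual labels in {+1, -1}, both classes present.
#' @param decision numeric decision values, same length.
#' @param threshold decision threshold (default 0).
#' @return An object of class `confusion_summary`: list with `TP`, `FP`,
#'   `TN`, `FN`, `sensitivity`, `specificity`, `balanced_accuracy`, `ppv`,
#'   `positive_likelihood_ratio`, `f_measure`.
#' @examples
#' s <- confusion_from_decisions(c(1, 1, -1, -1), c(0.8, 0.2, -0.5, 0.1))
#' s$balanced_accuracy
#' @export
confusion_from_decisions <- function(actual, decision, threshold = 0) {
  if (length(actual) == 0L) stop("empty input", call. = FALSE)
  if (length(actual) != length(decision)) {
    stop("actual and decision must have equal length", call. = FALSE)
  }
  check_labels(actual)
  predicted <- ifelse(decision > threshold, 1, -1)
  TP <- sum(actual == 1 & predicted == 1)
  FN <- sum(actual == 1 & predicted == -1)
  TN <- sum(actual == -1 & predicted == -1)
  FP <- sum(actual == -1 & predicted == 1)
  confusion_summary(TP = TP, FP = FP, TN = TN, FN = FN)
}

#' @rdname confusion_from_decisions
#' @param TP,FP,TN,FN non-negative integer counts (alternative entry point
#'   when the confusion matrix is already known).
#' @export
confusion_summary <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_field("counts", "must be non-negative integers")
  }
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  ppv <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  lr <- if (spec < 1) sens / (1 - spec) else Inf
  f <- if (!is.na(ppv) && ppv + sens > 0) 2 * ppv * sens / (ppv + sens)
       else NA_real_
  structure(
    list(TP = TP, FP = FP, TN = TN, FN = FN,
         sensitivity = sens, specificity = spec,
         balanced_accuracy = (sens + spec) / 2,
         ppv = ppv, positive_likelihood_ratio = lr, f_measure = f),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(
    paste0("confusion: TP=%d FP=%d TN=%d FN=%d\n",
           "sensitivity %.1f%%  specificity %.1f%%  balanced accuracy %.1f%%\n",
           "PPV %.1f%%  LR+ %.2f  F-measure %.2f\n"),
    x$TP, x$FP, x$TN, x$FN, 100 * x$sensitivity, 100 * x$specificity,
    100 * x$balanced_accuracy, 100 * x$ppv, x$positive_likelihood_ratio,
    x$f_measure))
  invisible(x)
}

#' Beta-posterior credible interval for balanced accuracy
#'
#' Places independent uniform-prior beta posteriors on sensitivity and
#' specificity, `Sens ~ Beta(TP + 1, FN + 1)` and
#' `Spec ~ Beta(TN + 1, FP + 1)`, and reports a central credible interval
#' for the balanced accuracy `B = (Sens + Spec) / 2` from Monte-Carlo
#' draws. Note that the posterior mean of B is pulled toward 1/2 by the
#' uniform priors and is *not* the sample balanced accuracy that
#' [confusion_from_decisions()] reports; the interval is the uncertainty
#' statement around that headline number.
#'
#' @param summary a `confusion_summary` (or anything with TP/FP/TN/FN).
#' @param level credible level in (0, 1), default 0.95.
#' @param draws number of Monte-Carlo draws (default 1e6).
#' @param seed RNG seed for reproducibility.
#' @return An object of class `posterior_interval`: list with `lower`,
#'   `upper`, `level`, `posterior_mean`, `draws`.
#' @export
balanced_posterior_interval <- function(summary, level = 0.95,
                                        draws = 1e6, seed = 1L) {
  if (length(level) != 1L || level <= 0 || level >= 1) {
    abort_field("level", "must be in (0, 1)")
  }
  with(summary, {
    if (any(c(TP, FP, TN, FN) < 0)) abort_field("counts", "must be >= 0")
    b <- with_seed(seed, {
      (stats::rbeta(draws, TP + 1, FN + 1) +
         stats::rbeta(draws, TN + 1, FP + 1)) / 2
    })
    q <- unname(stats::quantile(b, c((1 - level) / 2, (1 + level) / 2)))
    structure(
      list(lower = q[1], upper = q[2], level = level,
           posterior_mean = mean(b), draws = draws),
      class = "posterior_interval"
    )
  })
}

#' ROC curve and AUC from decision values
#'
#' The AUC is computed by exhaustive pair counting: the fraction of
#' (positive, negative) subject pairs in which the positive subject has the
#' larger decision value, ties counted one half. This equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param actual labels in {+1, -1}.
#' @param decision decision values.
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`,
#'   starting at (0, 0)) and `auc`.
#' @export
roc_points_and_auc <- function(actual, decision) {
  check_labels(actual)
  pos <- decision[actual == 1]
  neg <- decision[actual == -1]
  wins <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  auc <- mean(wins)
  thr <- sort(unique(decision), decreasing = TRUE)
  points <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(neg >= t), numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(pos >= t), numeric(1))))
  list(points = points, auc = auc)
}

#' Precision-recall curve from decision values
#'
#' Precision and recall at every distinct decision-value threshold, in
#' descending threshold order (prediction rule: decision >= threshold).
#'
#' @inheritParams roc_points_and_auc
#' @return Data frame with columns `threshold`, `recall`, `precision`.
#' @export
precision_recall_points <- function(actual, decision) {
  check_labels(actual)
  thr <- sort(unique(decision), decreasing = TRUE)
  n_pos <- sum(actual == 1)
  rows <- lapply(thr, function(t) {
    called <- decision >= t
    data.frame(threshold = t,
               recall = sum(actual == 1 & called) / n_pos,
               precision = sum(actual == 1 & called) / sum(called))
  })
  do.call(rbind, rows)
}

#' Assemble the full performance report for a set of predictions
#'
#' @param actual labels in {+1, -1}.
#' @param decision decision values.
#' @param level credible level for the balanced-accuracy interval.
#' @param draws Monte-Carlo draws for the interval.
#' @param seed interval RNG seed.
#' @return List with `confusion` (a `confusion_summary`), `interval`
#'   (a `posterior_interval`), `roc` and `pr`.
#' @export
evaluate_predictions <- function(actual, decision, level = 0.95,
                                 draws = 1e6, seed = 1L) {
  cs <- confusion_from_decisions(actual, decision)
  list(confusion = cs,
       interval = balanced_posterior_interval(cs, level, draws, seed),
       roc = roc_points_and_auc(actual, decision),
       pr = precision_recall_points(actual, decision))
}
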