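#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (predicting
#' malignant when `score >= threshold`) and integrates the resulting
#' (FPR, TPR) staircase with the trapezoidal rule. With this tie handling
#' the AUC equals the Mann-Whitney statistic `U / (n1 * n2)` of the scores.
#'
#' @param scores numeric scores (higher = more likely malignant).
#' @param truth labels, `"malignant"` (positive) / `"benign"`.
#' @return A list of class `roc_curve`: data frame `points` (threshold,
#'   fpr, tpr) and scalar `auc`.
#' @export
roc_auc <- function(scores, truth) {
  pos <- truth == "malignant"
  if (!any(pos) || all(pos))
    stop("both classes must be present in truth", call. = FALSE)
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_curve")
}

#' Net reclassification improvement (binary labels)
#'
#' Quantifies how much a new classifier improves on an old one, per class:
#' among true malignant cases, `event_net` is the net fraction reclassified
#' from wrong to right (`up`) minus right to wrong (`down`); `nonevent_net`
#' is the same among true benign cases; `nri` is their sum. For binary
#' labels this equals the change in sensitivity plus the change in
#' specificity, and ranges over [-2, 2].
#'
#' @param new_pred,old_pred predicted labels of the new and old method.
#' @param truth true labels; both classes must be present.
#' @return A list of class `nri_result`: `nri`, `event_net`,
#'   `nonevent_net`, and the up/down counts per class.
#' @export
nri <- function(new_pred, old_pred, truth) {
  stopifnot(length(new_pred) == length(truth),
            length(old_pred) == length(truth))
  if (!all(c("malignant", "benign") %in% truth))
    stop("both classes must be present in truth", call. = FALSE)
  net <- function(cls) {
    i <- truth == cls
    up <- sum(old_pred[i] != cls & new_pred[i] == cls)
    down <- sum(old_pred[i] == cls & new_pred[i] != cls)
    list(net = (up - down) / sum(i), up = up, down = down)
  }
  ev <- net("malignant")
  ne <- net("benign")
  structure(list(nri = ev$net + ne$net,
                 event_net = ev$net, nonevent_net = ne$net,
                 events_up = ev$up, events_down = ev$down,
                 nonevents_up = ne$up, nonevents_down = ne$down),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("NRI = %.4g (events %+0.4g, non-events %+0.4g)\n",
              x$nri, x$event_net, x$nonevent_net))
  invisible(x)
}
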