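#' 2-step threshold classification of a single feature value
#'
#' Step 1 (interval rule): if the value lies within one SD of exactly one
#' training group's mean, it is assigned to that group. Step 2 (nearest
#' mean): if it lies within both bands, or within neither, it is assigned
#' to the group with the nearer mean (absolute distance) and flagged
#' ambiguous. A tie in distance goes to malignant — the conservative call
#' in cancer triage.
#'
#' @param value the case's feature value.
#' @param malignant_stats,benign_stats numeric `(mean, sd)` pairs of the
#'   training groups; both SDs must be positive.
#' @param case_id optional identifier carried into the outcome.
#' @return A list of class `classification_outcome`: `case_id`, `predicted`
#'   (`"malignant"`/`"benign"`), `step` (`"interval"` or `"nearest-mean"`),
#'   `ambiguous`.
#' @examples
#' threshold_classify(900, c(1098, 295), c(1443, 462))   # interval step
#' threshold_classify(2000, c(1098, 295), c(1443, 462))  # nearest mean
#' @export
threshold_classify <- function(value, malignant_stats, benign_stats,
                               case_id = NA_character_) {
  stopifnot(is.finite(value), length(malignant_stats) >= 2,
            length(benign_stats) >= 2)
  if (malignant_stats[2] <= 0 || benign_stats[2] <= 0)
    stop("group SD must be > 0 for threshold classification", call. = FALSE)
  in_mal <- abs(value - malignant_stats[1]) <= malignant_stats[2]
  in_ben <- abs(value - benign_stats[1]) <= benign_stats[2]
  if (xor(in_mal, in_ben)) {
    predicted <- if (in_mal) "malignant" else "benign"
    step <- "interval"; ambiguous <- FALSE
  } else {
    d_mal <- abs(value - malignant_stats[1])
    d_ben <- abs(value - benign_stats[1])
    predicted <- if (d_mal <= d_ben) "malignant" else "benign"
    step <- "nearest-mean"; ambiguous <- TRUE
  }
  structure(list(case_id = case_id, predicted = predicted, step = step,
                 ambiguous = ambiguous, probability = NA_real_),
            class = "classification_outcome")
}

outcome_metrics <- function(predicted, truth, scheme, per_case = NULL,
                            auc = NA_real_) {
  tp <- sum(predicted == "malignant" & truth == "malignant")
  tn <- sum(predicted == "benign" & truth == "benign")
  fn <- sum(predicted == "benign" & truth == "malignant")
  fp <- sum(predicted == "malignant" & truth == "benign")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(sensitivity = sens, specificity = spec,
                 accuracy = (tp + tn) / length(truth),
                 balanced_accuracy = (sens + spec) / 2,
                 auc = auc, n = length(truth),
                 n_ambiguous = if (is.null(per_case)) NA_integer_ else
                   sum(vapply(per_case, `[[`, TRUE, "ambiguous")),
                 per_case = per_case, scheme = scheme),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf(
    "<cv_metrics %s> n=%d  sens=%.3f  spec=%.3f  acc=%.3f  bal.acc=%.3f",
    x$scheme, x$n, x$sensitivity, x$specificity, x$accuracy,
    x$balanced_accuracy))
  if (is.finite(x$auc)) cat(sprintf("  AUC=%.3f", x$auc))
  if (!is.na(x$n_ambiguous)) cat(sprintf("  ambiguous=%d", x$n_ambiguous))
  cat("\n")
  invisible(x)
}

#' Leave-one-out cross-validated threshold classification
#'
#' Each case is held out in turn; the malignant and benign mean/SD of the
#' chosen feature are recomputed from the remaining cases, and the held-out
#' case is classified with [threshold_classify()]. Malignant is the
#' positive class for sensitivity.
#'
#' @param records list of [feature_record()]s (both groups present; every
#'   leave-one-out fold must retain >= 2 cases per group).
#' @param feature feature name to classify on.
#' @param sample_sd use n-1 SDs instead of population SDs.
#' @return A `cv_metrics` list with per-case `classification_outcome`s.
#' @export
loocv_threshold <- function(records, feature, sample_sd = FALSE) {
  groups <- vapply(records, `[[`, "", "group")
  vals <- vapply(records, function(r) {
    v <- r$features[[feature]]
    if (is.null(v)) stop("record '", r$case_id, "' lacks feature '",
                         feature, "'", call. = FALSE)
    as.numeric(v)
  }, 0)
  ids <- vapply(records, `[[`, "", "case_id")
  if (sum(groups == "malignant") < 2L || sum(groups == "benign") < 2L)
    stop("need >= 2 records per group", call. = FALSE)
  mom <- function(x) {
    denom <- if (sample_sd) length(x) - 1L else length(x)
    s <- sqrt(sum((x - mean(x))^2) / denom)
    if (s <= 0) stop("group SD is 0 in a leave-one-out fold; feature '",
                     feature, "' is constant", call. = FALSE)
    c(mean(x), s)
  }
  per_case <- vector("list", length(records))
  for (i in seq_along(records)) {
    g <- groups[-i]; v <- vals[-i]
    if (sum(g == "malignant") < 2L || sum(g == "benign") < 2L)
      stop("leave-one-out fold leaves < 2 cases in a group", call. = FALSE)
    per_case[[i]] <- threshold_classify(
      vals[i], mom(v[g == "malignant"]), mom(v[g == "benign"]),
      case_id = ids[i])
  }
  predicted <- vapply(per_case, `[[`, "", "predicted")
  outcome_metrics(predicted, groups, scheme = "LOOCV", per_case = per_case)
}
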