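#' Synthetic minority oversampling (SMOTE)
#'
#' Each synthetic sample is `x_i + u * (x_nn - x_i)` with `u ~ Uniform(0,1)`
#' and `x_nn` one of the `k` nearest minority neighbours of a randomly
#' chosen minority point `x_i` (Euclidean distance) — so all synthetic
#' points lie on segments between minority points, inside their convex hull.
#'
#' @param minority numeric matrix, one minority-class sample per row.
#' @param n_new number of synthetic samples to generate.
#' @param k neighbourhood size; must be smaller than the minority count.
#' @param seed optional RNG seed for reproducibility.
#' @return A `n_new` x `ncol(minority)` matrix of synthetic samples.
#' @export
smote <- function(minority, n_new, k = 5L, seed = NULL) {
  minority <- as.matrix(minority)
  n <- nrow(minority)
  if (n < 2L) stop("SMOTE needs >= 2 minority samples", call. = FALSE)
  if (k >= n) stop("SMOTE neighbourhood k = ", k,
                   " must be < minority size ", n, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dmat <- as.matrix(stats::dist(minority))
  diag(dmat) <- Inf
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) nn[i, ] <- order(dmat[i, ])[seq_len(k)]
  out <- matrix(NA_real_, n_new, ncol(minority))
  base_idx <- sample.int(n, n_new, replace = TRUE)
  nn_pick <- sample.int(k, n_new, replace = TRUE)
  u <- stats::runif(n_new)
  for (j in seq_len(n_new)) {
    xi <- minority[base_idx[j], ]
    xn <- minority[nn[base_idx[j], nn_pick[j]], ]
    out[j, ] <- xi + u[j] * (xn - xi)
  }
  colnames(out) <- colnames(minority)
  out
}

stratified_folds <- function(groups, folds) {
  fold_of <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < folds)
      stop("class '", g, "' has ", length(idx), " cases; fewer than ",
           folds, " folds", call. = FALSE)
    fold_of[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  fold_of
}

#' Cross-validated KNN / SVM classification with SMOTE balancing
#'
#' Stratified k-fold cross-validation of a machine-learning classifier over
#' the repository features. Within each fold, features are z-scored by the
#' training-fold statistics and SMOTE oversamples the training minority
#' class to parity (never the held-out cases, avoiding leakage). Each
#' held-out case receives a probability of malignancy; the label is the
#' more probable class, and a case is flagged ambiguous when its winning
#' probability is in (0.5, 0.8] — at most moderate confidence.
#'
#' Models: `"KNN"` (k nearest neighbours, probability = malignant fraction
#' among the k votes, via [class::knn()]) and `"SVM"` (radial-basis
#' support vector machine, C = 1, Platt-calibrated probabilities, via
#' [e1071::svm()]).
#'
#' @param records list of [feature_record()]s with both groups present.
#' @param model `"KNN"` or `"SVM"`.
#' @param features feature names to use; default the reference clinical set
#'   of [select_features()].
#' @param folds number of CV folds (default 10).
#' @param seed RNG seed controlling fold assignment, SMOTE and model
#'   internals; identical seeds give identical results.
#' @param knn_k neighbours for KNN.
#' @param ambiguity probability interval `(lo, hi]` flagged ambiguous.
#' @return A `cv_metrics` list (sensitivity, specificity, accuracy,
#'   balanced accuracy, AUC over held-out probabilities, per-case outcomes).
#' @export
model_cv <- function(records, model = c("KNN", "SVM"), features = NULL,
                     folds = 10L, seed = 1L, knn_k = 5L,
                     ambiguity = c(0.5, 0.8)) {
  model <- match.arg(model)
  features <- features %||% select_features(list(), preset = "reference")$selected
  groups <- vapply(records, `[[`, "", "group")
  ids <- vapply(records, `[[`, "", "case_id")
  if (!all(c("malignant", "benign") %in% groups))
    stop("both groups must be present", call. = FALSE)
  X <- features_matrix(records, features)
  set.seed(seed)
  fold_of <- stratified_folds(groups, folds)
  prob_mal <- rep(NA_real_, length(records))
  for (fd in seq_len(folds)) {
    test <- fold_of == fd
    Xtr <- X[!test, , drop = FALSE]; gtr <- groups[!test]
    if (length(unique(gtr)) < 2L)
      stop("a class is absent from a training fold", call. = FALSE)
    mu <- colMeans(Xtr)
    sg <- apply(Xtr, 2, stats::sd)
    sg[sg == 0] <- 1
    Ztr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
    Zte <- sweep(sweep(X[test, , drop = FALSE], 2, mu), 2, sg, "/")
    # oversample the training minority to parity
    tab <- table(gtr)
    minority <- names(tab)[which.min(tab)]
    deficit <- max(tab) - min(tab)
    n_min <- min(tab)
    if (deficit > 0 && n_min >= 2L) {
      k_eff <- min(knn_k, n_min - 1L)
      syn <- smote(Ztr[gtr == minority, , drop = FALSE], deficit, k = k_eff)
      Ztr <- rbind(Ztr, syn)
      gtr <- c(gtr, rep(minority, deficit))
    }
    if (model == "KNN") {
      pred <- class::knn(Ztr, Zte, cl = factor(gtr), k = knn_k, prob = TRUE,
                         use.all = TRUE)
      win <- attr(pred, "prob")
      prob_mal[test] <- ifelse(pred == "malignant", win, 1 - win)
    } else {
      fit <- e1071::svm(Ztr, factor(gtr), kernel = "radial", cost = 1,
                        probability = TRUE)
      pr <- attr(stats::predict(fit, Zte, probability = TRUE),
                 "probabilities")
      prob_mal[test] <- pr[, "malignant"]
    }
  }
  predicted <- ifelse(prob_mal >= 0.5, "malignant", "benign")
  win_prob <- pmax(prob_mal, 1 - prob_mal)
  per_case <- lapply(seq_along(records), function(i)
    structure(list(case_id = ids[i], predicted = predicted[i],
                   step = "model",
                   ambiguous = win_prob[i] > ambiguity[1] &&
                     win_prob[i] <= ambiguity[2],
                   probability = prob_mal[i]),
              class = "classification_outcome"))
  auc <- roc_auc(prob_mal, groups)$auc
  out <- outcome_metrics(predicted, groups,
                         scheme = sprintf("%d-fold", folds),
                         per_case = per_case, auc = auc)
  out$model <- model
  out$probabilities <- prob_mal
  out
}
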