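# Mann-Whitney, feature selection, 2-step threshold rule, LOOCV, SMOTE,
# model CV, ROC/AUC, NRI.

test_that("Mann-Whitney U and exact P match enumeration for small groups", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_raw, 0.1)
  expect_true(r$exact)

  # symmetry with ties: identical groups give U = n1*n2/2
  expect_equal(mann_whitney_u(c(1, 2), c(1, 2))$U, 2)
  expect_error(mann_whitney_u(5, numeric(0)), "non-empty")

  # enumeration oracle across random tie-free group sizes up to 7
  set.seed(13)
  for (i in 1:12) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    v <- sample(1000, n1 + n2)  # distinct -> no ties
    a <- v[seq_len(n1)]; b <- v[-seq_len(n1)]
    r <- mann_whitney_u(a, b)
    expect_true(r$exact)
    expect_equal(r$p_raw, oracle_mw_exact_p(a, b), tolerance = 1e-12)
    expect_equal(r$U, sum(outer(a, b, ">")))
  }
})

test_that("feature selection finds separated features and applies Bonferroni", {
  recs <- two_group_records(10, 10, 0, 8, sd = 1, seed = 2,
                            feature_names_used = c("mean", "median"))
  sel <- select_features(recs)
  expect_setequal(sel$selected, c("mean", "median"))
  expect_equal(sel$tests$p_adjusted,
               pmin(1, sel$tests$p_raw * sel$m))

  # the reference preset bypasses testing
  preset <- select_features(list(), preset = "reference")
  expect_identical(preset$selected,
                   c("mean", "median", "kurtosis", "skewness", "entropy",
                     "c15", "c75"))

  # a raw P of .004 with 15 comparisons is not significant once corrected
  expect_equal(stats::p.adjust(0.004, "bonferroni", n = 15), 0.06)

  # corrected selection is never more permissive than raw selection
  recs2 <- two_group_records(6, 6, 0, 1.2, sd = 1, seed = 5,
                             feature_names_used = c("mean", "median",
                                                    "entropy"))
  raw <- suppressWarnings(select_features(recs2, use_correction = FALSE))
  cor <- suppressWarnings(select_features(recs2, use_correction = TRUE))
  expect_true(all(cor$selected %in% raw$selected))
})

test_that("correlation pruning keeps one member per correlated cluster", {
  set.seed(6)
  n <- 12
  base_m <- rnorm(n, 0, 1); base_b <- rnorm(n, 4, 1)
  mk <- function(i, g, v) feature_record(
    sprintf("%s%02d", g, i), g, "ADC",
    list(mean = v, median = v + rnorm(1, 0, 1e-3), entropy = rnorm(1)))
  recs <- c(lapply(1:n, function(i) mk(i, "malignant", base_m[i])),
            lapply(1:n, function(i) mk(i, "benign", base_b[i])))
  sel <- suppressWarnings(
    select_features(recs, correlation_prune = 0.9))
  # mean and median are near-duplicates: only one survives
  expect_length(intersect(sel$selected, c("mean", "median")), 1L)
})

test_that("2-step threshold rule reproduces the worked group-statistics examples", {
  st <- reference_group_stats()
  mal <- c(st$malignant$mean[["mean"]], st$malignant$sd[["mean"]])
  ben <- c(st$benign$mean[["mean"]], st$benign$sd[["mean"]])

  # ADC mean 900: inside the malignant band [803, 1393] only -> step 1
  o1 <- threshold_classify(900, mal, ben)
  expect_identical(o1$predicted, "malignant")
  expect_identical(o1$step, "interval")
  expect_false(o1$ambiguous)

  # kurtosis 2.1: inside both bands -> nearest mean (0 vs 0.069) -> malignant
  o2 <- threshold_classify(2.1,
                           c(st$malignant$mean[["kurtosis"]],
                             st$malignant$sd[["kurtosis"]]),
                           c(st$benign$mean[["kurtosis"]],
                             st$benign$sd[["kurtosis"]]))
  expect_identical(o2$predicted, "malignant")
  expect_identical(o2$step, "nearest-mean")
  expect_true(o2$ambiguous)

  # ADC mean 2000: inside neither band -> nearest mean (557 vs 902) -> benign
  o3 <- threshold_classify(2000, mal, ben)
  expect_identical(o3$predicted, "benign")
  expect_identical(o3$step, "nearest-mean")
  expect_true(o3$ambiguous)

  # equidistant tie goes to malignant
  o4 <- threshold_classify(0, c(-1, 0.1), c(1, 0.1))
  expect_identical(o4$predicted, "malignant")

  expect_error(threshold_classify(1, c(0, 0), c(1, 1)), "SD must be > 0")
})

test_that("threshold rule is equivariant under positive affine rescaling", {
  set.seed(17)
  for (i in 1:25) {
    v <- rnorm(1, 0, 3)
    ms <- c(rnorm(1), runif(1, 0.1, 2))
    bs <- c(rnorm(1, 2), runif(1, 0.1, 2))
    a <- runif(1, 0.1, 10); c0 <- rnorm(1, 0, 50)
    o <- threshold_classify(v, ms, bs)
    ot <- threshold_classify(a * v + c0,
                             c(a * ms[1] + c0, a * ms[2]),
                             c(a * bs[1] + c0, a * bs[2]))
    expect_identical(ot$predicted, o$predicted)
    expect_identical(ot$step, o$step)
    expect_identical(ot$ambiguous, o$ambiguous)
  }
})

test_that("LOOCV threshold classification matches a literal replay", {
  recs <- two_group_records(22, 18, 0, 1.5, sd = 1, seed = 31)
  got <- loocv_threshold(recs, "mean")
  oc <- oracle_loocv(recs, "mean")
  expect_equal(got$sensitivity, oc[["sensitivity"]])
  expect_equal(got$specificity, oc[["specificity"]])
  expect_equal(got$accuracy, oc[["accuracy"]])
  expect_equal(got$n, 40L)
})

test_that("well-separated cohorts classify perfectly under LOOCV", {
  recs <- two_group_records(10, 10, 0, 100, sd = 1, seed = 3)
  m <- loocv_threshold(recs, "mean")
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)
})

test_that("LOOCV rejects constant features and starved folds", {
  recs <- two_group_records(5, 5, 1, 2, sd = 0, seed = 1)
  expect_error(loocv_threshold(recs, "mean"), "SD is 0")
  recs2 <- two_group_records(2, 5, 0, 5, sd = 1, seed = 1)
  expect_error(loocv_threshold(recs2, "mean"), "fold leaves < 2")
})

test_that("SMOTE interpolates inside the minority set, reproducibly", {
  minority <- matrix(c(0, 10), ncol = 1)
  syn <- smote(minority, n_new = 50, k = 1, seed = 5)
  expect_true(all(syn >= 0 & syn <= 10))

  same <- smote(matrix(rep(c(3, 7), 4), ncol = 2, byrow = TRUE),
                n_new = 10, k = 2, seed = 1)
  expect_true(all(same[, 1] == 3 & same[, 2] == 7))

  a <- smote(matrix(rnorm(20), ncol = 2), n_new = 15, k = 3, seed = 9)
  b <- smote(matrix(rnorm(20), ncol = 2), n_new = 15, k = 3, seed = 9)
  expect_false(identical(a, b))  # different minority sets
  set.seed(9); m <- matrix(rnorm(20), ncol = 2)
  s1 <- smote(m, n_new = 15, k = 3, seed = 4)
  s2 <- smote(m, n_new = 15, k = 3, seed = 4)
  expect_identical(s1, s2)

  # first synthetic sample equals the interpolation formula replayed by hand
  set.seed(4)
  n <- nrow(m)
  dmat <- as.matrix(dist(m)); diag(dmat) <- Inf
  nn <- t(apply(dmat, 1, function(d) order(d)[1:3]))
  bi <- sample.int(n, 15, replace = TRUE)
  np <- sample.int(3, 15, replace = TRUE)
  u <- runif(15)
  expected1 <- m[bi[1], ] + u[1] * (m[nn[bi[1], np[1]], ] - m[bi[1], ])
  expect_equal(as.numeric(s1[1, ]), as.numeric(expected1))

  expect_error(smote(minority, 5, k = 2), "must be <")
  # synthetic points stay in the convex hull (here: coordinate-wise range)
  m2 <- matrix(runif(30, -2, 2), ncol = 3)
  s3 <- smote(m2, 40, k = 4, seed = 2)
  for (j in 1:3) {
    expect_gte(min(s3[, j]), min(m2[, j]))
    expect_lte(max(s3[, j]), max(m2[, j]))
  }
})

test_that("KNN and SVM separate a well-separated cohort perfectly", {
  recs <- two_group_records(15, 15, 0, 12, sd = 1, seed = 7)
  for (mdl in c("KNN", "SVM")) {
    m <- model_cv(recs, mdl, features = c("mean", "median"), folds = 5,
                  seed = 2)
    expect_equal(m$accuracy, 1)
    expect_equal(m$auc, 1)
  }
})

test_that("model CV probabilities drive the ambiguity flag at 0.5/0.8", {
  recs <- two_group_records(20, 16, 0, 1.2, sd = 1, seed = 19)
  m <- model_cv(recs, "KNN", features = c("mean", "median"), folds = 4,
                seed = 3)
  win <- pmax(m$probabilities, 1 - m$probabilities)
  amb <- vapply(m$per_case, `[[`, TRUE, "ambiguous")
  expect_identical(amb, win > 0.5 & win <= 0.8)
  expect_true(any(amb))       # overlapping cohort has uncertain cases
  expect_true(all(win >= 0.5))
  # predicted label is the more probable class
  pred <- vapply(m$per_case, `[[`, "", "predicted")
  expect_identical(pred, ifelse(m$probabilities >= 0.5, "malignant",
                                "benign"))
})

test_that("model CV is seed-deterministic and AUC is null for permuted labels", {
  recs <- two_group_records(30, 30, 0, 0, sd = 1, seed = 23)  # no signal
  m1 <- model_cv(recs, "KNN", features = c("mean", "median"), folds = 5,
                 seed = 11)
  m2 <- model_cv(recs, "KNN", features = c("mean", "median"), folds = 5,
                 seed = 11)
  expect_identical(m1$probabilities, m2$probabilities)
  expect_lt(abs(m1$auc - 0.5), 0.1)
  s1 <- model_cv(recs, "SVM", features = c("mean", "median"), folds = 5,
                 seed = 11)
  s2 <- model_cv(recs, "SVM", features = c("mean", "median"), folds = 5,
                 seed = 11)
  expect_identical(s1$probabilities, s2$probabilities)
  expect_lt(abs(s1$auc - 0.5), 0.1)
})

test_that("ROC/AUC: worked examples, U-statistic identity, pROC cross-check", {
  r <- roc_auc(c(0.9, 0.8, 0.7), c("malignant", "malignant", "benign"))
  expect_equal(r$auc, 1)
  r2 <- roc_auc(rep(0.5, 6), rep(c("malignant", "benign"), 3))
  expect_equal(r2$auc, 0.5)
  r3 <- roc_auc(c(0.9, 0.8, 0.3),
                c("malignant", "benign", "malignant"))
  expect_equal(r3$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c("malignant", "malignant")), "both classes")

  set.seed(29)
  for (i in 1:10) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    scores <- c(rnorm(n1, 1), rnorm(n2))
    if (i %% 2) scores <- round(scores, 1)  # induce ties
    truth <- rep(c("malignant", "benign"), c(n1, n2))
    auc <- roc_auc(scores, truth)$auc
    U <- mann_whitney_u(scores[truth == "malignant"],
                        scores[truth == "benign"])$U
    expect_equal(auc, U / (n1 * n2), tolerance = 1e-12)
    proc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = scores, levels = c("benign", "malignant"),
      direction = "<", quiet = TRUE)))
    expect_equal(auc, proc_auc, tolerance = 1e-12)
  }
})

test_that("NRI: identity, maximum, worked counts, antisymmetry", {
  truth <- rep(c("malignant", "benign"), c(10, 5))
  old <- truth
  expect_equal(nri(old, old, truth)$nri, 0)

  all_wrong <- ifelse(truth == "malignant", "benign", "malignant")
  expect_equal(nri(truth, all_wrong, truth)$nri, 2)

  # 10 malignant: old 7 right -> new 9 right; 5 benign: old 3 -> new 4
  old2 <- c(rep("malignant", 7), rep("benign", 3),
            rep("benign", 3), rep("malignant", 2))
  new2 <- c(rep("malignant", 9), rep("benign", 1),
            rep("benign", 4), rep("malignant", 1))
  r <- nri(new2, old2, truth)
  expect_equal(r$event_net, 0.2)
  expect_equal(r$nonevent_net, 0.2)
  expect_equal(r$nri, 0.4)

  # antisymmetry and the delta-sensitivity + delta-specificity identity
  set.seed(37)
  for (i in 1:10) {
    t <- sample(c("malignant", "benign"), 30, replace = TRUE)
    if (length(unique(t)) < 2) next
    p1 <- sample(c("malignant", "benign"), 30, replace = TRUE)
    p2 <- sample(c("malignant", "benign"), 30, replace = TRUE)
    expect_equal(nri(p1, p2, t)$nri, -nri(p2, p1, t)$nri)
    sens <- function(p) mean(p[t == "malignant"] == "malignant")
    spec <- function(p) mean(p[t == "benign"] == "benign")
    expect_equal(nri(p1, p2, t)$nri,
                 (sens(p1) - sens(p2)) + (spec(p1) - spec(p2)))
  }
  expect_error(nri(rep("malignant", 3), rep("malignant", 3),
                   rep("malignant", 3)), "both classes")
})
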