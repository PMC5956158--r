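#' Mann-Whitney U test
#'
#' `U = sum over pairs [a_i > b_j] + 1/2 [a_i = b_j]`, computed by pair
#' counting. The two-sided P value is exact (distribution enumeration, via
#' [stats::wilcox.test()]) when both groups have at most 8 observations and
#' there are no ties, otherwise the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param a,b numeric value vectors (both non-empty).
#' @param feature optional feature name carried into the result.
#' @param exact_max largest per-group size for the exact P value.
#' @return A list of class `mw_test`: `feature`, `U`, `p_raw`, `n1`, `n2`,
#'   `exact`.
#' @export
mann_whitney_u <- function(a, b, feature = NA_character_, exact_max = 8L) {
  if (!length(a) || !length(b))
    stop("both groups must be non-empty", call. = FALSE)
  cmp <- outer(a, b, function(x, y) (x > y) + 0.5 * (x == y))
  U <- sum(cmp)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= exact_max && length(b) <= exact_max && !ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  structure(list(feature = feature, U = U, p_raw = p,
                 n1 = length(a), n2 = length(b), exact = exact),
            class = "mw_test")
}

#' Select discriminative features between tumor groups
#'
#' Runs the Mann-Whitney U test per feature between the malignant and benign
#' records, applies the Bonferroni correction over the number of features
#' tested, and keeps features with P < `alpha`. By default selection uses
#' the raw P values (with a warning listing features the corrected P would
#' drop); set `use_correction = TRUE` to select on corrected P.
#'
#' Optionally, clusters of mutually correlated features
#' (pairwise |Spearman rho| > `correlation_prune`) are pruned to their
#' single best member (smallest raw P): centiles of the same map are near
#' duplicates and inflate the feature set.
#'
#' `preset = "reference"` skips testing and returns the fixed clinical set
#' {mean, median, kurtosis, skewness, entropy, c15, c75}.
#'
#' @param records list of [feature_record()]s containing both groups.
#' @param alpha significance level (default 0.05).
#' @param use_correction select on Bonferroni-corrected P.
#' @param correlation_prune optional |Spearman rho| threshold in (0, 1].
#' @param features candidate features; default [feature_names()] present in
#'   all records.
#' @param preset `"none"` or `"reference"`.
#' @return A list of class `feature_selection`: `selected` (character),
#'   `tests` (data frame: feature, U, p_raw, p_adjusted, significant),
#'   `m` (number of comparisons).
#' @export
select_features <- function(records, alpha = 0.05, use_correction = FALSE,
                            correlation_prune = NULL, features = NULL,
                            preset = c("none", "reference")) {
  preset <- match.arg(preset)
  if (preset == "reference")
    return(structure(list(
      selected = c("mean", "median", "kurtosis", "skewness", "entropy",
                   "c15", "c75"),
      tests = NULL, m = 0L), class = "feature_selection"))
  groups <- vapply(records, `[[`, "", "group")
  ma <- records[groups == "malignant"]
  be <- records[groups == "benign"]
  if (length(ma) < 2L || length(be) < 2L)
    stop("need >= 2 records in each group", call. = FALSE)
  features <- features %||% intersect(
    feature_names(), Reduce(intersect, lapply(records, function(r)
      names(r$features))))
  mm <- features_matrix(ma, features)
  bm <- features_matrix(be, features)
  tests <- lapply(features, function(f)
    mann_whitney_u(mm[, f], bm[, f], feature = f))
  m <- length(features)
  p_raw <- vapply(tests, `[[`, 0, "p_raw")
  p_adj <- stats::p.adjust(p_raw, method = "bonferroni", n = m)
  sel_p <- if (use_correction) p_adj else p_raw
  significant <- sel_p < alpha
  if (!use_correction) {
    dropped <- features[p_raw < alpha & p_adj >= alpha]
    if (length(dropped))
      warning("selection uses raw P values; Bonferroni-corrected P would ",
              "drop: ", paste(dropped, collapse = ", "), call. = FALSE)
  }
  selected <- features[significant]
  if (!length(selected))
    warning("no feature passes the significance threshold", call. = FALSE)
  if (!is.null(correlation_prune) && length(selected) > 1L) {
    vals <- rbind(mm, bm)[, selected, drop = FALSE]
    rho <- abs(stats::cor(vals, method = "spearman"))
    keep <- rep(TRUE, length(selected))
    names(keep) <- selected
    ord <- selected[order(p_raw[match(selected, features)])]
    for (f in ord) {
      if (!keep[f]) next
      partners <- selected[keep & selected != f &
                             rho[f, selected] > correlation_prune]
      keep[partners] <- FALSE
    }
    selected <- selected[keep[selected]]
  }
  structure(list(
    selected = selected,
    tests = data.frame(feature = features,
                       U = vapply(tests, `[[`, 0, "U"),
                       p_raw = p_raw, p_adjusted = p_adj,
                       significant = significant),
    m = m), class = "feature_selection")
}
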