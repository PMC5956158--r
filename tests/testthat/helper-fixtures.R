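# Shared fixture builders. Everything is generated in code; nothing binary
# ships with the package.

protocol_bvalues <- c(0, 50, 100, 150, 600, 1000)

biexp_signal <- function(b, S0, D, Dstar, f)
  S0 * ((1 - f) * exp(-b * D) + f * exp(-b * (D + Dstar)))

# single-voxel series replicated over a small grid
uniform_dwi <- function(signals, bvalues, shape = c(2, 2, 1),
                        spacing = c(1, 1, 1)) {
  arr <- array(rep(signals, each = prod(shape)),
               dim = c(shape, length(signals)))
  dwi_series(arr, bvalues = bvalues, spacing = spacing)
}

# gaussian two-group feature records on a single scale
two_group_records <- function(n_mal, n_ben, mal_mean, ben_mean, sd = 1,
                              seed = 1, feature_names_used = c("mean",
                                                               "median")) {
  gs <- list(
    malignant = list(
      mean = stats::setNames(rep(mal_mean, length(feature_names_used)),
                             feature_names_used),
      sd = stats::setNames(rep(sd, length(feature_names_used)),
                           feature_names_used),
      n = n_mal),
    benign = list(
      mean = stats::setNames(rep(ben_mean, length(feature_names_used)),
                             feature_names_used),
      sd = stats::setNames(rep(sd, length(feature_names_used)),
                           feature_names_used),
      n = n_ben))
  generate_feature_cohort(cohort_spec(gs), seed = seed)
}

# brute-force feature oracle: direct formula evaluation on the raw values
oracle_features <- function(v, nbins = 256L) {
  n <- length(v)
  centile <- function(p) {
    s <- sort(v)
    h <- (n - 1) * p
    lo <- floor(h)
    s[lo + 1] + (h - lo) * (s[min(lo + 2, n)] - s[lo + 1])
  }
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m4 <- sum((v - m)^4) / n
  lo <- min(v); hi <- max(v)
  width <- (hi - lo) / nbins
  counts <- integer(nbins)
  for (x in v) {
    k <- if (width == 0) 1L else min(nbins, floor((x - lo) / width) + 1L)
    counts[k] <- counts[k] + 1L
  }
  p <- counts[counts > 0] / n
  list(mean = m, median = centile(0.5),
       c2 = centile(.02), c5 = centile(.05), c10 = centile(.10),
       c15 = centile(.15), c25 = centile(.25), c75 = centile(.75),
       c85 = centile(.85), c90 = centile(.90), c95 = centile(.95),
       c98 = centile(.98),
       skewness = m3 / m2^1.5, kurtosis = m4 / m2^2,
       entropy = -sum(p * log2(p)))
}

# exact two-sided Mann-Whitney P by enumerating all C(n1+n2, n1) labelings
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">") + 0.5 * outer(x, y, "=="))
  }
  us <- apply(utils::combn(length(pooled), n1), 2, u_of)
  u_obs <- u_of(seq_len(n1))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# literal replay of the leave-one-out threshold procedure
oracle_loocv <- function(records, feature) {
  groups <- vapply(records, `[[`, "", "group")
  vals <- vapply(records, function(r) r$features[[feature]], 0)
  pred <- character(length(records))
  for (i in seq_along(records)) {
    g <- groups[-i]; v <- vals[-i]
    st <- function(lab) {
      x <- v[g == lab]
      c(mean(x), sqrt(mean((x - mean(x))^2)))
    }
    ms <- st("malignant"); bs <- st("benign")
    in_m <- abs(vals[i] - ms[1]) <= ms[2]
    in_b <- abs(vals[i] - bs[1]) <= bs[2]
    pred[i] <- if (in_m && !in_b) "malignant"
    else if (in_b && !in_m) "benign"
    else if (abs(vals[i] - ms[1]) <= abs(vals[i] - bs[1])) "malignant"
    else "benign"
  }
  c(sensitivity = mean(pred[groups == "malignant"] == "malignant"),
    specificity = mean(pred[groups == "benign"] == "benign"),
    accuracy = mean(pred == groups))
}

# per-case lesion phantom cohort: fit maps, extract ADC features, archive
build_phantom_cohort <- function(n_per_group = 8, seed = 100,
                                 shape = c(10, 10, 3),
                                 d_mal = 0.8e-3, d_ben = 1.6e-3,
                                 d_cv = 0.1) {
  repo <- feature_repository()
  set.seed(seed)
  case_seeds <- sample.int(1e6, 2 * n_per_group)
  case_d <- c(stats::rnorm(n_per_group, d_mal, d_cv * d_mal),
              stats::rnorm(n_per_group, d_ben, d_cv * d_ben))
  groups <- rep(c("malignant", "benign"), each = n_per_group)
  for (i in seq_along(groups)) {
    tissues <- default_tissues()
    tissues[[groups[i]]]$D <- case_d[i]
    sp <- phantom_spec(shape = shape, snr_b0 = 60,
                       lesions = list(list(center = c(5.5, 5.5, 2),
                                           radii = c(3.5, 3.5, 1.2),
                                           tissue = groups[i])),
                       tissues = tissues)
    ph <- generate_phantom(sp, seed = case_seeds[i])
    adc <- map_in_reporting_units(compute_adc_map(ph$dwi))
    vals <- extract_roi_values(adc, ph$rois[[1]])
    fv <- compute_features(vals, voxel_volume_mm3 = prod(adc$spacing))
    repo <- add_record(repo, feature_record(
      sprintf("case%02d", i), groups[i], "ADC", fv))
  }
  repo
}
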