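#' Reference ADC histogram-feature statistics for pediatric body tumors
#'
#' Published group means and SDs of the seven discriminative ADC histogram
#' features (diffusivities in 1e-6 mm^2/s) for malignant and benign solid
#' pediatric body tumors, with the cohort sizes (37 malignant, 11 benign).
#' These parameterize the default synthetic feature cohort and the worked
#' threshold-classifier examples.
#'
#' @return A list with per-group `mean` and `sd` named vectors and `n`.
#' @export
reference_group_stats <- function() {
  feats <- c("mean", "median", "kurtosis", "skewness", "entropy",
             "c15", "c75")
  list(
    malignant = list(
      mean = stats::setNames(
        c(1098, 996, 2.1, 0.02, 7.1, 710, 1319), feats),
      sd = stats::setNames(
        c(295, 262, 0.09, 0.004, 0.42, 201, 329), feats),
      n = 37L),
    benign = list(
      mean = stats::setNames(
        c(1443, 1442, 2.031, 0.0007, 6.85, 1072, 1683), feats),
      sd = stats::setNames(
        c(462, 511, 0.11, 0.01, 0.4, 406, 538), feats),
      n = 11L))
}

#' Phantom specification
#'
#' Describes a digital DWI phantom: grid, acquisition scheme, ellipsoidal
#' lesions, and the IVIM tissue parameters per label. Defaults mirror a
#' pediatric body DWI protocol: 6 b-values (0, 50, 100, 150, 600,
#' 1000 s/mm^2) in 3 orthogonal directions, 1.56 x 1.56 x 5 mm voxels, and
#' signal-to-noise ~60 on the b = 0 images.
#'
#' @param shape integer grid dimensions.
#' @param spacing voxel dimensions, mm.
#' @param bvalues acquisition b-values (s/mm^2).
#' @param directions gradient directions per b-value.
#' @param snr_b0 signal-to-noise ratio at b = 0 (`Inf` = noise free).
#' @param lesions list of lesions, each
#'   `list(center = c(x,y,z), radii = c(rx,ry,rz), tissue = label)`
#'   in 1-based voxel coordinates.
#' @param tissues named list of tissue parameter sets
#'   `list(S0, D, Dstar, f)` (diffusivities mm^2/s); must include
#'   `"background"` and every lesion label.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 8L),
                         spacing = c(1.56, 1.56, 5),
                         bvalues = c(0, 50, 100, 150, 600, 1000),
                         directions = 3L,
                         snr_b0 = 60,
                         lesions = list(list(center = c(16, 16, 4),
                                             radii = c(8, 8, 2.5),
                                             tissue = "malignant")),
                         tissues = default_tissues()) {
  stopifnot(length(shape) == 3L, all(shape >= 1L), snr_b0 > 0,
            directions >= 1L, "background" %in% names(tissues))
  for (ls in lesions) {
    if (!ls$tissue %in% names(tissues))
      stop("lesion tissue '", ls$tissue, "' has no parameter set",
           call. = FALSE)
    if (any(ls$center - ls$radii < 0.5) || any(ls$center + ls$radii > shape + 0.5))
      stop("lesion extends outside the grid", call. = FALSE)
  }
  structure(list(shape = as.integer(shape), spacing = spacing,
                 bvalues = bvalues, directions = as.integer(directions),
                 snr_b0 = snr_b0, lesions = lesions, tissues = tissues),
            class = "phantom_spec")
}

#' Default phantom tissue parameters
#'
#' Physiologically plausible IVIM parameter sets (diffusivities in mm^2/s):
#' a cellular "malignant" lesion (restricted diffusion, modest perfusion),
#' a looser "benign" lesion (faster diffusion, higher perfusion fraction),
#' and soft-tissue background.
#'
#' @return Named list of `list(S0, D, Dstar, f)` per tissue label.
#' @export
default_tissues <- function() {
  list(background = list(S0 = 1000, D = 1.5e-3, Dstar = 20e-3, f = 0.12),
       malignant  = list(S0 = 1100, D = 0.8e-3, Dstar = 12e-3, f = 0.08),
       benign     = list(S0 = 1050, D = 1.6e-3, Dstar = 25e-3, f = 0.18))
}

ellipsoid_mask <- function(shape, center, radii) {
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  r <- ((g$x - center[1]) / radii[1])^2 + ((g$y - center[2]) / radii[2])^2 +
       ((g$z - center[3]) / radii[3])^2
  array(r <= 1, dim = shape)
}

#' Generate a DWI phantom with known IVIM ground truth
#'
#' Builds the noise-free biexponential signal
#' `S(b) = S0 ((1-f) exp(-bD) + f exp(-b(D + D*)))` per voxel and
#' acquisition, then applies Rician corruption
#' `S' = sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ Normal(0, sigma)` and
#' `sigma` = mean background S0 / `snr_b0` — the noise model of magnitude
#' MR images.
#'
#' @param spec a [phantom_spec()].
#' @param seed RNG seed for the noise draw (ignored when noise free).
#' @return A list: `dwi` ([dwi_series()]), `truth` (named list of
#'   noise-free `parametric_map`s `D`, `Dstar`, `f`, `S0`), `rois` (one
#'   [roi_mask()] per lesion), `labels` (tissue-label array), `sigma`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  labels <- array("background", dim = shape)
  rois <- list()
  for (i in seq_along(spec$lesions)) {
    ls <- spec$lesions[[i]]
    m <- ellipsoid_mask(shape, ls$center, ls$radii)
    labels[m] <- ls$tissue
    rois[[sprintf("lesion%d_%s", i, ls$tissue)]] <-
      roi_mask(m, spacing = spec$spacing, label = ls$tissue)
  }
  par_of <- function(name) {
    v <- vapply(spec$tissues, `[[`, 0, name)
    array(v[labels], dim = shape)
  }
  S0 <- par_of("S0"); D <- par_of("D"); Ds <- par_of("Dstar"); f <- par_of("f")
  acq_b <- rep(spec$bvalues, each = spec$directions)
  acq_dir <- rep(seq_len(spec$directions) - 1L, times = length(spec$bvalues))
  if (spec$directions == 1L) acq_dir <- rep(-1L, length(acq_b))
  signal <- array(NA_real_, dim = c(shape, length(acq_b)))
  for (a in seq_along(acq_b))
    signal[, , , a] <- ivim_model(acq_b[a], S0, D, Ds, f)
  sigma <- 0
  if (is.finite(spec$snr_b0)) {
    sigma <- mean(S0[labels == "background"]) / spec$snr_b0
    set.seed(seed)
    n1 <- array(stats::rnorm(length(signal), 0, sigma), dim = dim(signal))
    n2 <- array(stats::rnorm(length(signal), 0, sigma), dim = dim(signal))
    signal <- sqrt((signal + n1)^2 + n2^2)
  }
  dwi <- dwi_series(signal, bvalues = acq_b, direction_index = acq_dir,
                    spacing = spec$spacing, series_id = "phantom")
  truth <- list(
    D = parametric_map(D, "IVIM-D", spec$spacing),
    Dstar = parametric_map(Ds, "IVIM-Dstar", spec$spacing),
    f = parametric_map(f, "IVIM-f", spec$spacing),
    S0 = parametric_map(S0, "S0", spec$spacing))
  list(dwi = dwi, truth = truth, rois = rois, labels = labels, sigma = sigma)
}

#' Cohort specification for the synthetic feature generator
#'
#' @param group_stats per-group feature means/SDs as returned by
#'   [reference_group_stats()] (the default).
#' @param n named per-group record counts; defaults to the reference cohort
#'   sizes carried in `group_stats`.
#' @param correlation optional equicorrelation in [0, 1) between features
#'   (on the z scale); the default 0 draws features independently.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_stats = reference_group_stats(), n = NULL,
                        correlation = 0) {
  stopifnot(correlation >= 0, correlation < 1)
  if (is.null(n))
    n <- vapply(group_stats, function(g) as.integer(g$n %||% 2L), 0L)
  n <- vapply(n, as.integer, 0L)
  stopifnot(all(n >= 2L))
  structure(list(group_stats = group_stats, n = n,
                 correlation = correlation),
            class = "cohort_spec")
}

#' Generate a synthetic two-group feature cohort
#'
#' Draws each case's features from per-group Gaussians
#' `Normal(mean_g, sd_g)` (optionally equicorrelated across features), then
#' enforces the centile-ordering invariant by sorting any centile features
#' within each record. A Gaussian surrogate of a real cohort: marginal
#' locations and spreads are honoured, the full dependence structure of
#' real histogram features is not.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed.
#' @param map_kind map kind stamped on the records.
#' @return A list of [feature_record()]s (`<group><index>` case ids).
#' @export
generate_feature_cohort <- function(spec = cohort_spec(), seed = 1L,
                                    map_kind = "ADC") {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  records <- list()
  for (g in names(spec$group_stats)) {
    gs <- spec$group_stats[[g]]
    feats <- names(gs$mean)
    centiles <- grep("^c[0-9]+$", feats, value = TRUE)
    cent_order <- centiles[order(as.numeric(sub("^c", "", centiles)))]
    for (i in seq_len(spec$n[[g]])) {
      z <- stats::rnorm(length(feats))
      if (spec$correlation > 0) {
        shared <- stats::rnorm(1)
        z <- sqrt(spec$correlation) * shared +
          sqrt(1 - spec$correlation) * z
      }
      vals <- gs$mean + gs$sd * z
      if (length(cent_order) > 1L)
        vals[cent_order] <- sort(vals[cent_order])
      rec <- feature_record(sprintf("%s%03d", g, i),
                            group = if (g %in% c("malignant", "benign")) g
                                    else "unknown",
                            map_kind = map_kind,
                            features = as.list(vals))
      records[[length(records) + 1L]] <- rec
    }
  }
  records
}
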