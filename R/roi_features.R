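#' Extract finite map values inside an ROI
#'
#' @param map a [parametric_map()].
#' @param roi an [roi_mask()] on the same grid.
#' @return Numeric vector of finite values at mask voxels, with attribute
#'   `n_dropped` = number of masked voxels that were `NaN`/infinite.
#' @export
extract_roi_values <- function(map, roi) {
  stopifnot(inherits(map, "parametric_map"), inherits(roi, "roi_mask"))
  if (!identical(dim(map$values), dim(roi$mask)))
    stop("map grid ", paste(dim(map$values), collapse = "x"),
         " does not match ROI grid ", paste(dim(roi$mask), collapse = "x"),
         call. = FALSE)
  if (!any(roi$mask)) stop("ROI contains no voxels", call. = FALSE)
  v <- map$values[roi$mask]
  keep <- is.finite(v)
  if (!any(keep))
    stop("ROI contains no finite map values", call. = FALSE)
  out <- v[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Equal-width histogram of ROI values
#'
#' `nbins` equal-width bins spanning `[min, max]` of the values; the maximum
#' value falls in the last bin. Constant input yields a single degenerate
#' bin of epsilon width, flagged via attribute `degenerate`.
#'
#' @param values numeric vector (>= 1 finite value).
#' @param nbins number of bins (>= 1).
#' @return A list of class `roi_histogram`: `bin_edges` (length nbins + 1)
#'   and integer `counts` (length nbins, summing to `length(values)`).
#' @export
compute_histogram <- function(values, nbins = 256L) {
  stopifnot(length(values) >= 1L, all(is.finite(values)), nbins >= 1L)
  lo <- min(values); hi <- max(values)
  degenerate <- hi <= lo
  if (degenerate) hi <- lo + max(abs(lo), 1) * .Machine$double.eps * 4
  edges <- seq(lo, hi, length.out = nbins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = nbins)
  structure(list(bin_edges = edges, counts = counts),
            class = "roi_histogram", degenerate = degenerate)
}

#' First-order histogram features of an ROI
#'
#' Computes the feature set used for tumor characterization: mean, median,
#' the 2/5/10/15/25/75/85/90/95/98th centiles, skewness, kurtosis, and
#' histogram entropy, plus voxel count and volume.
#'
#' Conventions (each recorded in the result):
#' * centiles from the raw values with linear interpolation at rank
#'   `h = (n-1) p` ([stats::quantile()] type 7);
#' * skewness `g1 = m3 / m2^1.5` and kurtosis `m4 / m2^2` (Pearson,
#'   non-excess; a normal distribution scores 3) from population
#'   (biased) central moments, switchable to sample-corrected moments;
#' * entropy `H = -sum p_i log2 p_i` in bits over the normalized counts of a
#'   `nbins`-bin equal-width histogram (`0 log 0 = 0`).
#'
#' Constant input gets skewness/kurtosis 0 and entropy 0, flagged
#' `degenerate`.
#'
#' @param values numeric vector of ROI values.
#' @param nbins histogram bins for the entropy (default 256).
#' @param voxel_volume_mm3 voxel volume used for `volume_ml` (optional).
#' @param sample_moments use unbiased sample moments instead of population
#'   moments for skewness/kurtosis.
#' @return A list of class `feature_vector`.
#' @export
compute_features <- function(values, nbins = 256L, voxel_volume_mm3 = NA_real_,
                             sample_moments = FALSE) {
  stopifnot(length(values) >= 1L, all(is.finite(values)))
  n <- length(values)
  probs <- c(2, 5, 10, 15, 25, 75, 85, 90, 95, 98) / 100
  cent <- stats::quantile(values, probs, type = 7, names = FALSE)
  m <- mean(values)
  dev <- values - m
  m2 <- mean(dev^2); m3 <- mean(dev^3); m4 <- mean(dev^4)
  degenerate <- n < 2L || m2 <= 0
  if (degenerate) {
    skew <- 0; kurt <- 0
  } else if (sample_moments) {
    s <- stats::sd(values)
    skew <- n / ((n - 1) * (n - 2)) * sum(dev^3) / s^3
    kurt <- if (n > 3)
      (n * (n + 1)) / ((n - 1) * (n - 2) * (n - 3)) * sum(dev^4) / s^4 -
        3 * (n - 1)^2 / ((n - 2) * (n - 3)) + 3
    else NA_real_
  } else {
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
  }
  h <- compute_histogram(values, nbins)
  p <- h$counts / sum(h$counts)
  entropy <- if (degenerate) 0 else -sum(ifelse(p > 0, p * log2(p), 0))
  fv <- list(mean = m, median = stats::median(values),
             c2 = cent[1], c5 = cent[2], c10 = cent[3], c15 = cent[4],
             c25 = cent[5], c75 = cent[6], c85 = cent[7], c90 = cent[8],
             c95 = cent[9], c98 = cent[10],
             skewness = skew, kurtosis = kurt, entropy = entropy,
             n_voxels = n,
             volume_ml = n * voxel_volume_mm3 / 1000)
  structure(fv, class = "feature_vector", nbins = as.integer(nbins),
            degenerate = degenerate,
            moment_convention = if (sample_moments) "sample" else "population")
}

#' Names of the scalar histogram features
#'
#' @param centiles include the centile features.
#' @return Character vector of feature names as used in feature records.
#' @export
feature_names <- function(centiles = TRUE) {
  c("mean", "median",
    if (centiles) c("c2", "c5", "c10", "c15", "c25", "c75", "c85", "c90",
                    "c95", "c98"),
    "skewness", "kurtosis", "entropy")
}

#' ROI morphology
#'
#' Volume, axis-aligned bounding lengths, center of mass (mean 0-based voxel
#' index per axis) and surface voxel count (mask voxels with fewer than 6
#' face neighbours inside the mask).
#'
#' @param roi an [roi_mask()].
#' @return A list of class `roi_morphology`: `volume_mm3`, `volume_ml`,
#'   `bounding_lengths_mm`, `center_of_mass`, `surface_voxel_count`,
#'   `n_voxels`.
#' @export
roi_morphology <- function(roi) {
  stopifnot(inherits(roi, "roi_mask"))
  if (!any(roi$mask)) stop("ROI contains no voxels", call. = FALSE)
  idx <- which(roi$mask, arr.ind = TRUE)
  n <- nrow(idx)
  vox_vol <- prod(roi$spacing)
  extent <- apply(idx, 2, function(i) max(i) - min(i) + 1L)
  com <- colMeans(idx) - 1  # 0-based voxel coordinates
  d <- dim(roi$mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- roi$mask
  inner <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] +
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] +
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] +
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] +
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] +
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  surface <- sum(inner & nb < 6)
  structure(list(volume_mm3 = n * vox_vol,
                 volume_ml = n * vox_vol / 1000,
                 bounding_lengths_mm = as.numeric(extent * roi$spacing),
                 center_of_mass = as.numeric(com),
                 surface_voxel_count = as.integer(surface),
                 n_voxels = n),
            class = "roi_morphology")
}
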