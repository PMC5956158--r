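#' Multi-b-value diffusion-weighted series
#'
#' A `dwi_series` bundles a 4-D signal array with its acquisition metadata:
#' one 3-D frame per (b-value, gradient direction) acquisition. This is the
#' common input container for ADC and IVIM map computation.
#'
#' @param signal 4-D non-negative numeric array indexed `(x, y, z, acquisition)`.
#'   A 3-D array is accepted and treated as a single acquisition.
#' @param bvalues numeric vector of diffusion weightings (s/mm^2), one per
#'   acquisition (4th-axis slab).
#' @param direction_index integer vector, one per acquisition: gradient
#'   direction id 0..2, or -1 for a trace(-weighted) frame. Defaults to all -1.
#' @param spacing numeric length-3 voxel dimensions in mm.
#' @param series_id free-text identifier.
#'
#' @return An object of class `dwi_series` with fields `signal`, `bvalues`,
#'   `direction_index`, `spacing`, `series_id`.
#' @examples
#' arr <- array(1000, dim = c(4, 4, 2, 2))
#' dwi <- dwi_series(arr, bvalues = c(0, 1000))
#' @export
dwi_series <- function(signal, bvalues, direction_index = NULL,
                       spacing = c(1, 1, 1), series_id = "series") {
  if (length(dim(signal)) == 3L) dim(signal) <- c(dim(signal), 1L)
  stopifnot(length(dim(signal)) == 4L)
  nacq <- dim(signal)[4]
  if (is.null(direction_index)) direction_index <- rep(-1L, nacq)
  x <- structure(
    list(signal = signal,
         bvalues = as.numeric(bvalues),
         direction_index = as.integer(direction_index),
         spacing = as.numeric(spacing),
         series_id = as.character(series_id)),
    class = "dwi_series")
  validate_dwi_series(x)
  x
}

validate_dwi_series <- function(x) {
  nacq <- dim(x$signal)[4]
  if (length(x$bvalues) != nacq)
    stop("b-value count mismatch: ", length(x$bvalues), " b-values for ",
         nacq, " frames", call. = FALSE)
  if (length(x$direction_index) != nacq)
    stop("direction count mismatch: ", length(x$direction_index),
         " direction ids for ", nacq, " frames", call. = FALSE)
  if (any(x$bvalues < 0)) stop("b-values must be >= 0", call. = FALSE)
  if (length(x$spacing) != 3L || any(x$spacing <= 0))
    stop("spacing must be 3 positive voxel dimensions (mm)", call. = FALSE)
  invisible(x)
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dwi_series '%s'> %dx%dx%d voxels, %d acquisitions\n",
              x$series_id, d[1], d[2], d[3], d[4]))
  cat("  b-values:", paste(unique(x$bvalues), collapse = ", "), "s/mm^2\n")
  cat("  spacing:", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' Combine gradient directions into trace-weighted frames
#'
#' Reduces a per-direction series to one frame per b-value by taking the
#' voxel-wise geometric mean across directions, the trace-weighted signal
#' used for isotropic diffusion analysis. Frames already marked as trace
#' (direction -1) must be the only frame for their b-value.
#'
#' A voxel that is zero in any direction has geometric mean zero; the count
#' of such voxels is attached as attribute `n_zero_voxels`.
#'
#' @param dwi a [dwi_series()].
#' @return A `dwi_series` with one frame per distinct b-value (sorted
#'   ascending) and all direction ids -1.
#' @export
combine_directions <- function(dwi) {
  validate_dwi_series(dwi)
  bs <- sort(unique(dwi$bvalues))
  d <- dim(dwi$signal)
  counts <- table(dwi$bvalues)
  if (length(unique(counts)) > 1L)
    stop("unequal direction coverage per b-value: ",
         paste(sprintf("b=%s has %d frame(s)", names(counts), counts),
               collapse = "; "), call. = FALSE)
  out <- array(NA_real_, dim = c(d[1:3], length(bs)))
  n_zero <- 0L
  for (i in seq_along(bs)) {
    idx <- which(dwi$bvalues == bs[i])
    frames <- dwi$signal[, , , idx, drop = FALSE]
    # geometric mean across the acquisition axis; exact zero annihilates
    gm <- exp(apply(log(pmax(frames, 0)), 1:3, mean))
    gm[apply(frames == 0, 1:3, any)] <- 0
    n_zero <- n_zero + sum(apply(frames == 0, 1:3, any))
    out[, , , i] <- gm
  }
  res <- dwi_series(out, bvalues = bs, direction_index = rep(-1L, length(bs)),
                    spacing = dwi$spacing, series_id = dwi$series_id)
  attr(res, "n_zero_voxels") <- n_zero
  res
}

#' Quantitative parametric map
#'
#' A 3-D map of a voxel-wise quantity derived from the DWI signal. Invalid
#' voxels are encoded as `NA`/`NaN`, never as sentinel numbers.
#'
#' @param values 3-D numeric array.
#' @param kind one of `"ADC"`, `"IVIM-D"`, `"IVIM-Dstar"`, `"IVIM-f"`, `"S0"`.
#' @param spacing numeric length-3 voxel dimensions in mm.
#' @param units unit string; defaults to `"mm^2/s"` for diffusivities,
#'   `"1"` (dimensionless) for IVIM-f, `"a.u."` for S0.
#' @return An object of class `parametric_map`.
#' @export
parametric_map <- function(values, kind, spacing = c(1, 1, 1), units = NULL) {
  kind <- match.arg(kind, map_kinds())
  if (length(dim(values)) != 3L) stop("map values must be a 3-D array", call. = FALSE)
  if (is.null(units))
    units <- switch(kind, "IVIM-f" = "1", "S0" = "a.u.", "mm^2/s")
  fin <- values[is.finite(values)]
  if (kind == "IVIM-f" && length(fin) && (min(fin) < -1e-9 || max(fin) > 1 + 1e-9))
    stop("IVIM-f values must lie in [0,1] or be NaN", call. = FALSE)
  if (kind %in% c("ADC", "IVIM-D", "IVIM-Dstar") && length(fin) && min(fin) < 0)
    stop(kind, " values must be >= 0 or NaN", call. = FALSE)
  structure(list(values = values, kind = kind, units = units,
                 spacing = as.numeric(spacing)),
            class = "parametric_map")
}

map_kinds <- function() c("ADC", "IVIM-D", "IVIM-Dstar", "IVIM-f", "S0")

#' @export
print.parametric_map <- function(x, ...) {
  d <- dim(x$values)
  fin <- x$values[is.finite(x$values)]
  cat(sprintf("<parametric_map %s [%s]> %dx%dx%d, %d valid voxels",
              x$kind, x$units, d[1], d[2], d[3], length(fin)))
  if (length(fin)) cat(sprintf(", median %.4g", stats::median(fin)))
  cat("\n")
  invisible(x)
}

#' Rescale a diffusivity map to reporting units
#'
#' Diffusivities are held internally in mm^2/s; clinical tables typically
#' print them in 1e-6 mm^2/s (so 1.098e-3 mm^2/s prints as 1098). This
#' multiplies ADC / IVIM-D / IVIM-Dstar values by 1e6 and relabels the units;
#' dimensionless maps are returned unchanged.
#'
#' @param map a [parametric_map()].
#' @return A `parametric_map` in reporting units.
#' @export
map_in_reporting_units <- function(map) {
  stopifnot(inherits(map, "parametric_map"))
  if (!map$kind %in% c("ADC", "IVIM-D", "IVIM-Dstar") ||
      identical(map$units, "1e-6 mm^2/s")) return(map)
  parametric_map(map$values * 1e6, kind = map$kind, spacing = map$spacing,
                 units = "1e-6 mm^2/s")
}

#' Binary region-of-interest mask
#'
#' @param mask 3-D logical (or 0/1 numeric) array; `TRUE` = inside the ROI.
#' @param spacing numeric length-3 voxel dimensions in mm.
#' @param label free-text ROI label.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, spacing = c(1, 1, 1), label = "roi") {
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array", call. = FALSE)
  m <- array(as.logical(mask), dim = dim(mask))
  structure(list(mask = m, spacing = as.numeric(spacing),
                 label = as.character(label)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<roi_mask '%s'> %dx%dx%d, %d voxels inside\n",
              x$label, d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}
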