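#' Read a multi-b-value DWI series
#'
#' Reads a 4-D diffusion-weighted series from either a DICOM series
#' (a directory of `.dcm` files, see [read_dwi_dicom()]) or a NIfTI-1 volume
#' with a JSON sidecar. The sidecar sits next to the image as
#' `<stem>.json` and must contain `"bvalues"` (one per 4th-axis frame) and
#' optionally `"directions"` (gradient direction id per frame, -1 = trace).
#'
#' @param path a NIfTI file (`.nii`/`.nii.gz`) or a DICOM directory.
#' @param format_hint optional `"nifti"` or `"dicom"`; inferred from `path`
#'   when omitted.
#' @return A [dwi_series()] with one 3-D frame per acquisition, in stored
#'   acquisition order, with b-values taken from metadata.
#' @export
read_dwi_series <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  fmt <- format_hint %||% if (dir.exists(path)) "dicom" else "nifti"
  switch(match.arg(fmt, c("nifti", "dicom")),
         dicom = read_dwi_dicom(path),
         nifti = read_dwi_nifti(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sidecar_path <- function(path) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(stem, ".json")
}

read_dwi_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing b-value metadata: no JSON sidecar at ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$bvalues))
    stop("missing b-value metadata: sidecar ", sc, " has no 'bvalues' field",
         call. = FALSE)
  nacq <- dim(arr)[4]
  if (length(meta$bvalues) != nacq)
    stop("b-value count mismatch: sidecar lists ", length(meta$bvalues),
         " b-values but image has ", nacq, " frames", call. = FALSE)
  dirs <- meta$directions %||% rep(-1L, nacq)
  dwi_series(arr, bvalues = meta$bvalues, direction_index = dirs,
             spacing = RNifti::pixdim(img)[1:3],
             series_id = basename(sub("\\.nii(\\.gz)?$", "", path)))
}

#' Write a DWI series as NIfTI + JSON sidecar
#'
#' @param dwi a [dwi_series()].
#' @param path output `.nii` or `.nii.gz` file; the sidecar is written next
#'   to it.
#' @return `path`, invisibly.
#' @export
write_dwi_nifti <- function(dwi, path) {
  validate_dwi_series(dwi)
  arr <- dwi$signal
  attr(arr, "pixdim") <- c(dwi$spacing, 1)
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  jsonlite::write_json(
    list(bvalues = dwi$bvalues, directions = dwi$direction_index),
    sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Write / read a parametric map as NIfTI
#'
#' The map kind and units travel in a JSON sidecar (`<stem>.json`) so the
#' round trip preserves values (to float precision), kind, units and voxel
#' spacing; invalid voxels stay `NaN`.
#'
#' @param map a [parametric_map()].
#' @param path `.nii`/`.nii.gz` file.
#' @param datatype storage type passed to RNifti; the default `"double"`
#'   keeps the round trip lossless.
#' @return `write_parametric_map()` returns `path` invisibly;
#'   `read_parametric_map()` returns a `parametric_map`.
#' @export
write_parametric_map <- function(map, path, datatype = "double") {
  stopifnot(inherits(map, "parametric_map"))
  arr <- map$values
  attr(arr, "pixdim") <- map$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = datatype), path)
  jsonlite::write_json(list(kind = map$kind, units = map$units),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_parametric_map
#' @export
read_parametric_map <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing map sidecar ", sc, " (kind/units unknown)", call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$kind) || !meta$kind %in% map_kinds())
    stop("unknown map kind in sidecar: ", meta$kind %||% "<missing>",
         call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)  # singleton z dropped
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < 3L) spacing <- c(spacing, rep(1, 3 - length(spacing)))
  parametric_map(arr, kind = meta$kind, spacing = spacing[1:3],
                 units = meta$units)
}

#' Read an ROI mask onto a reference map grid
#'
#' Nonzero voxels become `TRUE`. The mask must share the reference grid;
#' masks on a different grid are nearest-neighbour resampled only when
#' `resample = TRUE` (binary labels survive nearest-neighbour, unlike
#' interpolation).
#'
#' @param path NIfTI mask file.
#' @param reference a [parametric_map()] defining the target grid.
#' @param resample allow nearest-neighbour resampling onto the reference
#'   grid when shapes differ.
#' @param label ROI label; defaults to the file stem.
#' @return An [roi_mask()] on the reference grid.
#' @export
read_roi_mask <- function(path, reference, resample = FALSE, label = NULL) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  stopifnot(inherits(reference, "parametric_map"))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)  # singleton z dropped
  m <- arr != 0
  ref_dim <- dim(reference$values)
  if (!identical(dim(m), ref_dim)) {
    if (!resample)
      stop("mask grid ", paste(dim(m), collapse = "x"),
           " does not match reference ", paste(ref_dim, collapse = "x"),
           "; pass resample = TRUE for nearest-neighbour resampling",
           call. = FALSE)
    m <- resample_mask_nn(m, ref_dim)
  }
  if (!any(m)) stop("ROI contains no voxels", call. = FALSE)
  roi_mask(m, spacing = reference$spacing,
           label = label %||% basename(sub("\\.nii(\\.gz)?$", "", path)))
}

#' @keywords internal
resample_mask_nn <- function(mask, target_dim) {
  src_dim <- dim(mask)
  # map each target voxel centre to the nearest source voxel (0-based centres
  # aligned at the grid corners)
  idx <- lapply(1:3, function(ax) {
    centres <- (seq_len(target_dim[ax]) - 0.5) / target_dim[ax] * src_dim[ax]
    pmin(pmax(ceiling(centres), 1L), src_dim[ax])
  })
  out <- mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  dim(out) <- target_dim
  out
}

#' Write an ROI mask as NIfTI (nonzero = inside)
#'
#' @param roi an [roi_mask()].
#' @param path output `.nii`/`.nii.gz` file.
#' @return `path`, invisibly.
#' @export
write_roi_mask <- function(roi, path) {
  stopifnot(inherits(roi, "roi_mask"))
  arr <- array(as.integer(roi$mask), dim = dim(roi$mask))
  attr(arr, "pixdim") <- roi$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), path)
  invisible(path)
}
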