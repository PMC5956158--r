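# Minimal DICOM support for diffusion-weighted series.
#
# Scope: Explicit VR Little Endian only, uncompressed 16-bit pixel data, one
# multi-frame file per (b-value, direction) acquisition. Enough to round-trip
# the phantom generator's output and to read the b-value / geometry metadata
# the pipeline needs; not a general DICOM implementation.

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_MR <- "1.2.840.10008.5.1.4.1.1.4"
# VRs that use the 4-byte length form (2-byte VR + 2 reserved + 4-byte length)
LONG_VRS <- c("OB", "OW", "OF", "OD", "SQ", "UC", "UR", "UT", "UN")

even_pad <- function(raw, pad = as.raw(0L)) {
  if (length(raw) %% 2L == 1L) c(raw, pad) else raw
}

dcm_element <- function(group, element, vr, value_raw) {
  value_raw <- even_pad(value_raw, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  hdr <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
           writeBin(as.integer(element), raw(), size = 2, endian = "little"),
           charToRaw(vr))
  if (vr %in% LONG_VRS) {
    hdr <- c(hdr, as.raw(c(0, 0)),
             writeBin(length(value_raw), raw(), size = 4, endian = "little"))
  } else {
    hdr <- c(hdr, writeBin(length(value_raw), raw(), size = 2, endian = "little"))
  }
  c(hdr, value_raw)
}

dcm_str <- function(group, element, vr, x)
  dcm_element(group, element, vr, charToRaw(paste(x, collapse = "\\")))
dcm_us <- function(group, element, x)
  dcm_element(group, element, "US", writeBin(as.integer(x), raw(), size = 2,
                                             endian = "little"))
dcm_fd <- function(group, element, x)
  dcm_element(group, element, "FD", writeBin(as.numeric(x), raw(), size = 8,
                                             endian = "little"))

new_uid <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    paste0("2.25.", format(as.numeric(Sys.time()) * 1000, scientific = FALSE,
                           trim = TRUE, digits = 13), ".", counter)
  }
})

#' Write a DWI series as a DICOM directory
#'
#' Writes one multi-frame Explicit-VR-little-endian file per acquisition
#' (`acq-001.dcm`, ...), each holding all slices of that (b, direction)
#' frame as 16-bit pixel data with a rescale slope. The b-value is stored in
#' the standard diffusion tag (0018,9087) and, when `private_bvalue = TRUE`
#' (the default, matching Siemens practice), also in the private tag
#' (0019,100C). The gradient direction id is encoded in (0018,9089) as the
#' corresponding Cartesian unit vector (zeros for trace frames).
#'
#' @param dwi a [dwi_series()].
#' @param dir output directory (created if needed).
#' @param standard_bvalue,private_bvalue which b-value tags to write; at
#'   least one must be `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_dwi_dicom <- function(dwi, dir, standard_bvalue = TRUE,
                            private_bvalue = TRUE) {
  validate_dwi_series(dwi)
  if (!standard_bvalue && !private_bvalue)
    stop("at least one b-value tag must be written", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(dwi$signal)
  series_uid <- new_uid()
  for (a in seq_len(d[4])) {
    frame <- dwi$signal[, , , a]
    mx <- max(frame)
    slope <- if (mx > 0) mx / 65535 else 1
    pix <- as.integer(round(frame / slope))
    # DICOM row-major order = columns (x) fastest, which is R's native order
    pix_raw <- writeBin(as.vector(pix), raw(), size = 2, endian = "little")
    dir_id <- dwi$direction_index[a]
    grad <- c(0, 0, 0)
    if (dir_id %in% 0:2) grad[dir_id + 1] <- 1
    sop_uid <- new_uid()
    ds <- c(
      dcm_str(0x0008, 0x0016, "UI", SOP_CLASS_MR),
      dcm_str(0x0008, 0x0018, "UI", sop_uid),
      dcm_str(0x0008, 0x0060, "CS", "MR"),
      dcm_str(0x0010, 0x0010, "PN", "PHANTOM"),
      dcm_str(0x0018, 0x0050, "DS", format(dwi$spacing[3])),
      dcm_str(0x0018, 0x0088, "DS", format(dwi$spacing[3])),
      if (standard_bvalue) dcm_fd(0x0018, 0x9087, dwi$bvalues[a]),
      dcm_fd(0x0018, 0x9089, grad),
      if (private_bvalue) c(
        dcm_str(0x0019, 0x0010, "LO", "SIEMENS MR HEADER"),
        dcm_str(0x0019, 0x100C, "IS", format(round(dwi$bvalues[a])))
      ),
      dcm_str(0x0020, 0x000E, "UI", series_uid),
      dcm_str(0x0020, 0x0013, "IS", format(a)),
      dcm_us(0x0028, 0x0002, 1),
      dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_str(0x0028, 0x0008, "IS", format(d[3])),
      dcm_us(0x0028, 0x0010, d[2]),      # rows = y
      dcm_us(0x0028, 0x0011, d[1]),      # columns = x
      dcm_str(0x0028, 0x0030, "DS", format(dwi$spacing[2:1])),
      dcm_us(0x0028, 0x0100, 16),
      dcm_us(0x0028, 0x0101, 16),
      dcm_us(0x0028, 0x0102, 15),
      dcm_us(0x0028, 0x0103, 0),
      dcm_str(0x0028, 0x1052, "DS", "0"),
      dcm_str(0x0028, 0x1053, "DS", sprintf("%.9g", slope)),
      dcm_element(0x7FE0, 0x0010, "OW", pix_raw)
    )
    meta_body <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      dcm_str(0x0002, 0x0002, "UI", SOP_CLASS_MR),
      dcm_str(0x0002, 0x0003, "UI", sop_uid),
      dcm_str(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_EXPLICIT_LE),
      dcm_str(0x0002, 0x0012, "UI", "2.25.4242424242")
    )
    meta <- c(dcm_element(0x0002, 0x0000, "UL",
                          writeBin(length(meta_body), raw(), size = 4,
                                   endian = "little")),
              meta_body)
    con <- file(file.path(dir, sprintf("acq-%03d.dcm", a)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
    close(con)
  }
  invisible(dir)
}

read_uint <- function(raw, size) {
  v <- readBin(raw, "integer", n = length(raw) / size, size = size,
               endian = "little", signed = size == 4)
  if (size == 2) v <- ifelse(v < 0, v + 65536L, v)
  v
}

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file: ", path, call. = FALSE)
  pos <- 133L
  elems <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- read_uint(raw[pos:(pos + 1)], 2)
    element <- read_uint(raw[(pos + 2):(pos + 3)], 2)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- read_uint(raw[(pos + 8):(pos + 11)], 4)
      val_start <- pos + 12L
    } else {
      len <- read_uint(raw[(pos + 6):(pos + 7)], 2)
      val_start <- pos + 8L
    }
    if (len < 0 || val_start + len - 1L > n)
      stop("corrupt DICOM element at offset ", pos, " in ", path, call. = FALSE)
    value <- if (len > 0) raw[val_start:(val_start + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, element)
    elems[[key]] <- list(vr = vr, value = value)
    pos <- val_start + len
  }
  elems
}

dcm_get_str <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NULL)
  v <- e$value[e$value != as.raw(0)]  # UI values are null-padded
  strsplit(trimws(rawToChar(v)), "\\\\")[[1]]
}
dcm_get_num <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NULL)
  if (e$vr == "FD") readBin(e$value, "double", n = length(e$value) / 8,
                            size = 8, endian = "little")
  else if (e$vr == "US") read_uint(e$value, 2)
  else if (e$vr == "UL") read_uint(e$value, 4)
  else as.numeric(dcm_get_str(elems, key))
}

#' Read a DWI series from a DICOM directory
#'
#' Reads every `.dcm` file in `path` (Explicit VR Little Endian,
#' uncompressed), sorts by instance number, and assembles one frame per
#' file. The b-value is taken from the standard diffusion tag (0018,9087)
#' when present, falling back to the Siemens private tag (0019,100C); a file
#' carrying neither is an error. The gradient direction id is recovered from
#' the diffusion gradient orientation vector (0018,9089) when present.
#'
#' @param path directory containing `.dcm` files.
#' @return A [dwi_series()].
#' @export
read_dwi_dicom <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("no .dcm files in ", path, call. = FALSE)
  parsed <- lapply(files, parse_dicom_file)
  inst <- vapply(parsed, function(e) dcm_get_num(e, "0020,0013") %||% NA_real_, 0)
  ord <- order(inst)
  parsed <- parsed[ord]
  frames <- list(); bvals <- numeric(0); dirs <- integer(0)
  spacing <- NULL; shape <- NULL
  for (i in seq_along(parsed)) {
    e <- parsed[[i]]
    b <- dcm_get_num(e, "0018,9087")
    if (is.null(b)) b <- dcm_get_num(e, "0019,100C")
    if (is.null(b) || !is.finite(b))
      stop("missing b-value metadata in ", basename(files[ord][i]),
           ": neither tag (0018,9087) nor (0019,100C) present", call. = FALSE)
    rows <- dcm_get_num(e, "0028,0010")
    cols <- dcm_get_num(e, "0028,0011")
    nframes <- dcm_get_num(e, "0028,0008") %||% 1
    pix <- e[["7FE0,0010"]]
    if (is.null(pix)) stop("no pixel data in ", basename(files[ord][i]),
                           call. = FALSE)
    v <- read_uint(pix$value[seq_len(2 * rows * cols * nframes)], 2)
    slope <- dcm_get_num(e, "0028,1053") %||% 1
    inter <- dcm_get_num(e, "0028,1052") %||% 0
    # stored row-major: fastest axis is columns (x); array() fills x first
    frame <- array(v * slope + inter, dim = c(cols, rows, nframes))
    sp <- c(rev(dcm_get_num(e, "0028,0030") %||% c(1, 1)),
            dcm_get_num(e, "0018,0088") %||% dcm_get_num(e, "0018,0050") %||% 1)
    this_shape <- c(cols, rows, nframes)
    if (is.null(shape)) { shape <- this_shape; spacing <- sp }
    else if (!identical(shape, this_shape))
      stop("inconsistent frame geometry: ", paste(shape, collapse = "x"),
           " vs ", paste(this_shape, collapse = "x"), call. = FALSE)
    grad <- dcm_get_num(e, "0018,9089")
    dir_id <- -1L
    if (!is.null(grad) && any(grad != 0)) dir_id <- which.max(abs(grad)) - 1L
    frames[[i]] <- frame
    bvals <- c(bvals, b)
    dirs <- c(dirs, dir_id)
  }
  signal <- array(unlist(frames), dim = c(shape, length(frames)))
  dwi_series(signal, bvalues = bvals, direction_index = dirs,
             spacing = spacing, series_id = basename(path))
}
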