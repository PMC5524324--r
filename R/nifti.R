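# Minimal NIfTI-1 reader/writer (single-file .nii, little-endian).
# Scalar images and displacement fields are stored as float64, label maps as
# uint8; geometry (spacing, origin) travels in pixdim and the qform offset.
# Only what this package writes is guaranteed to be read back; malformed
# files raise explicit parse errors.

NIFTI_DT_UINT8 <- 2L
NIFTI_DT_FLOAT32 <- 16L
NIFTI_DT_FLOAT64 <- 64L

write_nifti_raw <- function(data, dim_field, spacing, origin, datatype,
                            path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wi32 <- function(x) writeBin(as.integer(x), con, size = 4,
                               endian = "little")
  wi16 <- function(x) writeBin(as.integer(x), con, size = 2,
                               endian = "little")
  wf32 <- function(x) writeBin(as.numeric(x), con, size = 4,
                               endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  bitpix <- c(`2` = 8L, `16` = 32L, `64` = 64L)[[as.character(datatype)]]

  wi32(348)                       # sizeof_hdr
  wraw(10); wraw(18)              # data_type, db_name
  wi32(0); wi16(0)                # extents, session_error
  writeBin(charToRaw("r"), con)   # regular
  wraw(1)                         # dim_info
  wi16(dim_field)                 # dim[8]
  wf32(c(0, 0, 0))                # intent_p1..3
  wi16(0)                         # intent_code
  wi16(datatype); wi16(bitpix)
  wi16(0)                         # slice_start
  wf32(c(1, spacing, rep(1, 4)))  # pixdim[8] (qfac = 1)
  wf32(352)                       # vox_offset
  wf32(1); wf32(0)                # scl_slope, scl_inter
  wi16(0); wraw(1)                # slice_end, slice_code
  writeBin(as.raw(2L + 8L), con)  # xyzt_units: mm + s
  wf32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  wi32(0); wi32(0)                # glmax, glmin
  desc <- charToRaw("marmotbm phantom volume")
  writeBin(c(desc, raw(80 - length(desc))), con)
  wraw(24)                        # aux_file
  wi16(1); wi16(0)                # qform_code = 1, sform_code = 0
  wf32(c(0, 0, 0))                # quatern b, c, d (identity)
  wf32(origin)                    # qoffset x, y, z
  wf32(rep(0, 12))                # srow
  wraw(16)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wraw(4)                         # empty extension flag
  if (datatype == NIFTI_DT_UINT8) {
    writeBin(as.raw(as.integer(data)), con)
  } else if (datatype == NIFTI_DT_FLOAT32) {
    writeBin(as.numeric(data), con, size = 4, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = 8, endian = "little")
  }
  invisible(path)
}

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop("read_nifti: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri32 <- function(n = 1) readBin(con, "integer", n, size = 4,
                                  endian = "little")
  ri16 <- function(n = 1) readBin(con, "integer", n, size = 2,
                                  endian = "little")
  rf32 <- function(n = 1) readBin(con, "numeric", n, size = 4,
                                  endian = "little")
  hdr_size <- ri32()
  if (length(hdr_size) == 0 || hdr_size != 348)
    stop("read_nifti: not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  readBin(con, "raw", 36)                  # data_type..dim_info
  dim_field <- ri16(8)
  rf32(3); ri16(1)                         # intent
  datatype <- ri16(); bitpix <- ri16(); ri16(1)
  pixdim <- rf32(8)
  vox_offset <- rf32()
  scl_slope <- rf32(); scl_inter <- rf32()
  readBin(con, "raw", 120 - 116)           # slice_end..xyzt (2+1+1)
  rf32(4); ri32(2)
  readBin(con, "raw", 104)                 # descrip + aux_file
  ri16(2)                                  # qform, sform codes
  rf32(3)
  origin <- rf32(3)
  rf32(12)
  readBin(con, "raw", 16)                  # intent_name
  magic <- readBin(con, "raw", 4)
  if (!identical(rawToChar(magic[1:3]), "n+1"))
    stop("read_nifti: unsupported magic (expected single-file 'n+1'): ", path)
  ndim <- dim_field[1]
  if (ndim < 3 || ndim > 5)
    stop("read_nifti: unsupported dimensionality: ", ndim)
  dims <- dim_field[2:(1 + ndim)]
  dims[dims == 0] <- 1L
  n <- prod(dims)
  seek(con, vox_offset)
  data <- switch(as.character(datatype),
    `2` = as.integer(readBin(con, "raw", n)),
    `4` = readBin(con, "integer", n, size = 2, endian = "little"),
    `8` = readBin(con, "integer", n, size = 4, endian = "little"),
    `16` = readBin(con, "numeric", n, size = 4, endian = "little"),
    `64` = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("read_nifti: unsupported datatype code ", datatype))
  if (length(data) != n)
    stop("read_nifti: truncated data section in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(data, dim = dims), spacing = pixdim[2:4],
       origin = origin, datatype = datatype)
}

#' Write / read a scalar volume as NIfTI-1
#'
#' Float64 on disk: write-then-read round-trips bit-exactly.
#' @param vol an [image_volume()]
#' @param path output `.nii` path
#' @return `write_volume` returns `path` invisibly; `read_volume` an
#'   [image_volume()]
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  sh <- vol$grid$shape
  write_nifti_raw(vol$data, c(3L, sh, 1L, 1L, 1L, 1L), vol$grid$spacing,
                  vol$grid$origin, NIFTI_DT_FLOAT64, path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  r <- read_nifti_raw(path)
  if (length(dim(r$data)) != 3) {
    if (length(dim(r$data)) == 4 && dim(r$data)[4] == 1)
      r$data <- array(r$data, dim = dim(r$data)[1:3])
    else stop("read_volume: expected a 3D scalar volume in ", path)
  }
  image_volume(r$data, grid_spec(dim(r$data), r$spacing, r$origin))
}

#' Write / read a label map as NIfTI-1 with a JSON dictionary sidecar
#'
#' Labels go to disk as unsigned 8-bit integers; the region dictionary is
#' written to `<path>.json` (or a caller-supplied sidecar path).
#' @param labels a [label_volume()]
#' @param path output `.nii` path
#' @param sidecar JSON sidecar path (default `paste0(path, ".json")`)
#' @return `write_labels` returns `path` invisibly; `read_labels` a
#'   [label_volume()]
#' @export
write_labels <- function(labels, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(labels, "label_volume"))
  if (max(labels$labels) > 255)
    stop("write_labels: label ids above 255 do not fit uint8")
  sh <- labels$grid$shape
  write_nifti_raw(labels$labels, c(3L, sh, 1L, 1L, 1L, 1L),
                  labels$grid$spacing, labels$grid$origin, NIFTI_DT_UINT8,
                  path)
  jsonlite::write_json(as.list(labels$dictionary), sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path, sidecar = paste0(path, ".json")) {
  r <- read_nifti_raw(path)
  if (length(dim(r$data)) == 4 && dim(r$data)[4] == 1)
    r$data <- array(r$data, dim = dim(r$data)[1:3])
  if (length(dim(r$data)) != 3)
    stop("read_labels: expected a 3D label volume in ", path)
  dict <- if (file.exists(sidecar)) {
    d <- jsonlite::read_json(sidecar)
    stats::setNames(as.integer(unlist(d)), names(d))
  } else region_dictionary()
  label_volume(array(as.integer(r$data), dim = dim(r$data)),
               grid_spec(dim(r$data), r$spacing, r$origin), dict)
}

#' Write / read a displacement field as 4D NIfTI-1
#'
#' Stored as a 4D volume whose last axis is the vector component (x, y, z),
#' in mm, float64.
#' @param field a [deformation_field()]
#' @param path output `.nii` path
#' @return `write_field` returns `path` invisibly; `read_field` a
#'   [deformation_field()]
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "deformation_field"))
  sh <- field$grid$shape
  write_nifti_raw(field$u, c(4L, sh, 3L, 1L, 1L, 1L), field$grid$spacing,
                  field$grid$origin, NIFTI_DT_FLOAT64, path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  r <- read_nifti_raw(path)
  d <- dim(r$data)
  if (length(d) != 4 || d[4] != 3)
    stop("read_field: expected a 4D field with 3 components in ", path)
  deformation_field(r$data, grid_spec(d[1:3], r$spacing, r$origin))
}

#' Write a transform as JSON / read it back
#' @param tr a [linear_transform()]
#' @param path output `.json` path
#' @return `write_transform` returns `path` invisibly; `read_transform` a
#'   [linear_transform()]
#' @export
write_transform <- function(tr, path) {
  stopifnot(inherits(tr, "linear_transform"))
  jsonlite::write_json(list(rot = tr$rot, trans = tr$trans, scale = tr$scale,
                            center = tr$center),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  linear_transform(x$rot, x$trans, x$scale, x$center)
}
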