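# Minimal NIfTI-1 I/O.
#
# Only what this package needs: single-file .nii / .nii.gz, little-endian,
# 3D volumes, datatypes uint8 (2), int16 (4), int32 (8), float32 (16),
# float64 (64). Spacing is carried in pixdim; a diagonal sform is written.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352

#' Read a NIfTI-1 volume
#'
#' Reads a single-file little-endian NIfTI-1 image (`.nii` or `.nii.gz`).
#' Supports 3D volumes with datatypes uint8, int16, int32, float32, float64.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (a 3D numeric array) and `spacing`
#'   (length-3 voxel size in mm).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(sizeof_hdr, NIFTI_HDR_SIZE))
    stop("not a little-endian NIfTI-1 file: ", path)
  readBin(con, "raw", 36L)                      # data_type, db_name, extents...
  dim_field <- readBin(con, "integer", 8L, size = 2L, endian = "little")
  ndim <- dim_field[1L]
  if (ndim < 3L || ndim > 4L) stop("only 3D NIfTI volumes are supported")
  dims <- dim_field[2:4]
  if (ndim == 4L && dim_field[5L] > 1L) stop("only 3D NIfTI volumes are supported")
  readBin(con, "raw", 14L)                      # intent_p1..3, intent_code
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "integer", 1L, size = 2L, endian = "little")  # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = "little")  # slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = "little")
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  scl_slope <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  scl_inter <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  # remainder of the header up to vox_offset (incl. any extension bytes)
  readBin(con, "raw", as.integer(round(vox_offset)) - 120L)
  n <- prod(dims)
  data <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n, size = 2L, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n, size = 4L, endian = "little")),
    "16" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8L, endian = "little"),
    stop("unsupported NIfTI datatype: ", datatype)
  )
  if (length(data) != n) stop("truncated NIfTI data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(data, dim = dims), spacing = pixdim[2:4])
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D array as a single-file little-endian NIfTI-1 image with a
#' diagonal sform built from `spacing`. Images are stored as float32,
#' binary masks as uint8.
#'
#' @param data 3D numeric array.
#' @param path Output path; gz-compressed when it ends in `.gz`.
#' @param spacing Length-3 voxel size in mm.
#' @param datatype `"float32"` or `"uint8"`.
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1),
                        datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L, all(spacing > 0))
  dims <- dim(data)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi(NIFTI_HDR_SIZE, 4L)
  wraw(36L)                                   # data_type, db_name, extents, ...
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2L)         # dim
  wraw(14L)                                   # intent_p*, intent_code
  dt_code <- if (datatype == "uint8") 2L else 16L
  bitpix <- if (datatype == "uint8") 8L else 32L
  wi(dt_code, 2L); wi(bitpix, 2L); wi(0L, 2L) # datatype, bitpix, slice_start
  wf(c(1, spacing, 0, 0, 0, 0))               # pixdim
  wf(NIFTI_VOX_OFFSET)                        # vox_offset
  wf(1); wf(0)                                # scl_slope, scl_inter
  wi(0L, 2L); wraw(2L)                        # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                           # cal_max, cal_min, slice_dur, toffset
  wi(c(0L, 0L), 4L)                           # glmax, glmin
  wraw(104L)                                  # descrip, aux_file
  wi(c(0L, 1L), 2L)                           # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                               # quatern_b/c/d, qoffset_x/y/z
  wf(c(spacing[1], 0, 0, 0))                  # srow_x
  wf(c(0, spacing[2], 0, 0))                  # srow_y
  wf(c(0, 0, spacing[3], 0))                  # srow_z
  wraw(16L)                                   # intent_name
  writeBin(charToRaw("n+1"), con); wraw(1L)   # magic
  wraw(4L)                                    # extension flag
  vals <- as.vector(data)
  if (datatype == "uint8") {
    writeBin(as.integer(round(vals)), con, size = 1L, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  }
  invisible(path)
}
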