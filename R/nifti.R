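# Minimal single-file NIfTI-1 I/O.
#
# The pipeline only needs to round-trip its own 3D/4D arrays (magnitude
# volumes, label maps, T2/S0/R2 maps), so this supports the plain ".nii"
# and ".nii.gz" single-file layout with scalar datatypes and an axis-aligned
# sform. It is validated in the test suite against nibabel.

NIFTI_DTYPES <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D or 4D array as a NIfTI-1 file
#'
#' @param data numeric or integer array with 3 or 4 dimensions.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size numeric length-3, mm per axis.
#' @param datatype one of `"float32"`, `"float64"`, `"int16"`, `"int32"`,
#'   `"uint8"`; integer arrays default to `"int32"`, doubles to `"float32"`.
#' @param t_step spacing along the 4th axis (echo index), stored in pixdim.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size = c(1, 1, 1),
                        datatype = NULL, t_step = 1) {
  nd <- length(dim(data))
  if (is.null(dim(data)) || !(nd %in% c(3L, 4L)))
    abort("write_nifti: 'data' must be a 3D or 4D array")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(datatype))
    datatype <- if (is.integer(data)) "int32" else "float32"
  dt <- NIFTI_DTYPES[[datatype]]
  if (is.null(dt)) abort("write_nifti: unsupported datatype '", datatype, "'")

  dims <- dim(data)
  dim8 <- integer(8)
  dim8[1] <- nd
  dim8[2:(1 + nd)] <- dims
  if (nd < 7L) dim8[(2 + nd):8] <- 1L
  pixdim <- c(1, voxel_size, t_step, 1, 1, 1)

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4, endian = "little")          # sizeof_hdr
  writeBin(raw(36), con)                                     # data_type..dim_info
  writeBin(as.integer(dim8), con, size = 2, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")     # intent_p1..p3
  writeBin(0L, con, size = 2, endian = "little")             # intent_code
  writeBin(dt$code, con, size = 2, endian = "little")        # datatype
  writeBin(dt$bitpix, con, size = 2, endian = "little")      # bitpix
  writeBin(0L, con, size = 2, endian = "little")             # slice_start
  writeBin(as.numeric(pixdim), con, size = 4, endian = "little")
  writeBin(352, con, size = 4, endian = "little")            # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")        # scl_slope, scl_inter
  writeBin(0L, con, size = 2, endian = "little")             # slice_end
  writeBin(raw(1), con)                                      # slice_code
  writeBin(as.raw(10L), con)                                 # xyzt_units: mm | s
  writeBin(numeric(4), con, size = 4, endian = "little")     # cal_max..toffset
  writeBin(integer(2), con, size = 4, endian = "little")     # glmax, glmin
  writeBin(raw(104), con)                                    # descrip, aux_file
  writeBin(c(0L, 1L), con, size = 2, endian = "little")      # qform_code, sform_code
  writeBin(numeric(6), con, size = 4, endian = "little")     # quatern, qoffset
  srow <- rbind(c(voxel_size[1], 0, 0, 0),
                c(0, voxel_size[2], 0, 0),
                c(0, 0, voxel_size[3], 0))
  writeBin(as.numeric(t(srow)), con, size = 4, endian = "little")
  writeBin(raw(16), con)                                     # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)                 # magic
  writeBin(raw(4), con)                                      # extension flag

  vals <- as.vector(data)
  if (dt$what == "integer") {
    vals <- as.integer(round(vals))
    writeBin(vals, con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written in the single-file layout
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a list with `data` (array), `voxel_size` (mm triple) and
#'   `datatype` (storage name).
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) abort("read_nifti: truncated header in ", path)
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = "little", signed = TRUE)
  }
  sizeof <- rd(0, "integer", 1, 4)
  if (sizeof != 348L) abort("read_nifti: not a little-endian NIfTI-1 file: ", path)
  dim8 <- rd(40, "integer", 8, 2)
  nd <- dim8[1]
  if (!(nd %in% c(2L, 3L, 4L))) abort("read_nifti: unsupported dimensionality ", nd)
  dims <- dim8[2:(1 + nd)]
  code <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)

  idx <- which(vapply(NIFTI_DTYPES, function(d) d$code == code, logical(1)))
  if (!length(idx)) abort("read_nifti: unsupported datatype code ", code)
  dt <- NIFTI_DTYPES[[idx]]

  # skip to the data offset (already consumed 348 bytes)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(dims)
  if (dt$what == "integer" && dt$size < 4L) {
    vals <- readBin(con, "integer", n = n, size = dt$size,
                    endian = "little", signed = dt$signed)
  } else {
    vals <- readBin(con, dt$what, n = n, size = dt$size, endian = "little")
  }
  if (length(vals) < n) abort("read_nifti: truncated data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = dims),
       voxel_size = pixdim[2:4],
       datatype = names(NIFTI_DTYPES)[idx])
}
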