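# Minimal NIfTI-1 I/O (single-file .nii, little-endian, float32/int16/uint8).
# No NIfTI reader ships with the supported R stack, so the 348-byte fixed
# header is written directly. Scope: 3D/4D scalar volumes with isotropic
# pixdim, no orientation matrices beyond a scaled identity s-form.

#' Write a 3D or 4D array as NIfTI-1
#'
#' @param arr numeric or integer array (3D or 4D).
#' @param path output path ending in `.nii`.
#' @param voxel_size voxel edge (mm), isotropic.
#' @param time_step spacing of the 4th dimension (min) for 4D arrays.
#' @param datatype `"float32"` or `"int16"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(arr, path, voxel_size = 1, time_step = 1,
                        datatype = c("float32", "int16")) {
  datatype <- match.arg(datatype)
  nd <- length(dim(arr))
  stopifnot(nd %in% c(3L, 4L))
  dims <- c(nd, dim(arr), rep(1L, 7 - nd))
  code <- switch(datatype, float32 = 16L, int16 = 4L)
  bitpix <- switch(datatype, float32 = 32L, int16 = 16L)

  con <- file(path, "wb")
  on.exit(close(con))
  wI <- function(x, size = 4L) writeBin(as.integer(x), con, size = size,
                                        endian = "little")
  wF <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wI(348L)                                  # 0   sizeof_hdr
  writeBin(raw(36L), con)                   # 4   data_type..dim_info
  wI(dims, size = 2L)                       # 40  dim[8]
  wF(c(0, 0, 0))                            # 56  intent_p1..p3
  wI(0L, 2L)                                # 68  intent_code
  wI(code, 2L)                              # 70  datatype
  wI(bitpix, 2L)                            # 72  bitpix
  wI(0L, 2L)                                # 74  slice_start
  wF(c(0, rep(voxel_size, 3), time_step, 0, 0, 0))  # 76 pixdim[8]
  wF(352)                                   # 108 vox_offset
  wF(1); wF(0)                              # 112 scl_slope, scl_inter
  wI(0L, 2L); writeBin(raw(1L), con); writeBin(raw(1L), con)  # 122..125
  wF(0); wF(0); wF(0); wF(0)                # cal_max..toffset
  wI(0L); wI(0L)                            # glmax, glmin (unused)
  writeBin(charToRaw(sprintf("%-80s", "braintransport"))[1:80], con)
  writeBin(raw(24L), con)                   # aux_file
  wI(0L, 2L); wI(1L, 2L)                    # qform_code=0, sform_code=1
  wF(rep(0, 6))                             # quatern b,c,d + qoffset x,y,z
  wF(c(voxel_size, 0, 0, 0))                # srow_x
  wF(c(0, voxel_size, 0, 0))                # srow_y
  wF(c(0, 0, voxel_size, 0))                # srow_z
  writeBin(raw(16L), con)                   # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1L), con)  # magic
  writeBin(raw(4L), con)                    # extension flag
  if (datatype == "float32") {
    writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  } else {
    writeBin(as.integer(arr), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()]
#'
#' Supports uncompressed single-file little-endian NIfTI-1 with datatypes
#' uint8, int16, int32, float32, float64.
#'
#' @param path path to a `.nii` file.
#' @return List with `data` (array), `voxel_size` (mm), `time_step`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  sz <- readBin(hdr[1:4], "integer", 1L, size = 4L, endian = "little")
  if (sz != 348L) stop_bt("not a little-endian NIfTI-1 file: %s", path)
  dims <- readBin(hdr[41:56], "integer", 8L, size = 2L, endian = "little")
  code <- readBin(hdr[71:72], "integer", 1L, size = 2L, endian = "little")
  pixdim <- readBin(hdr[77:108], "double", 8L, size = 4L, endian = "little")
  vox_offset <- readBin(hdr[109:112], "double", 1L, size = 4L,
                        endian = "little")
  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  n <- prod(shape)
  seek(con, vox_offset)
  data <- switch(as.character(code),
    "2"  = readBin(con, "integer", n, size = 1L, signed = FALSE),
    "4"  = readBin(con, "integer", n, size = 2L, endian = "little"),
    "8"  = readBin(con, "integer", n, size = 4L, endian = "little"),
    "16" = readBin(con, "double",  n, size = 4L, endian = "little"),
    "64" = readBin(con, "double",  n, size = 8L, endian = "little"),
    stop_bt("unsupported NIfTI datatype code %d", code))
  list(data = array(data, dim = shape), voxel_size = pixdim[2],
       time_step = if (nd >= 4) pixdim[5] else NA_real_)
}
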