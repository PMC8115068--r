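#' Minimal NIfTI-1 volume I/O
#'
#' Single-file (`.nii`), uncompressed, little-endian NIfTI-1 with an
#' identity-like affine (pixdim scaling only).  Supports the datatypes this
#' package emits: float64, float32, int32, int16 and uint8.  Written because
#' the runtime R stack ships no NIfTI reader; intentionally minimal - no
#' qform/sform rotations, extensions, or compressed variants.
#'
#' @param data Numeric or integer array, 3D or 4D.
#' @param path Output path (`.nii`).
#' @param voxel_size_mm Isotropic voxel size for pixdim (default 2).
#' @param datatype `"float32"` (default), `"float64"`, `"int16"`, `"int32"`
#'   or `"uint8"`.
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns the
#'   array with attribute `voxel_size_mm`.
#' @export
write_nifti <- function(data, path, voxel_size_mm = 2,
                        datatype = c("float32", "float64", "int16", "int32",
                                     "uint8")) {
  datatype <- match.arg(datatype)
  d <- dim(data)
  if (is.null(d) || !length(d) %in% 3:4) stop("data must be a 3D or 4D array")
  dt <- switch(datatype,
               uint8 = list(code = 2L, bits = 8L, what = "integer", size = 1L),
               int16 = list(code = 4L, bits = 16L, what = "integer", size = 2L),
               int32 = list(code = 8L, bits = 32L, what = "integer", size = 4L),
               float32 = list(code = 16L, bits = 32L, what = "double", size = 4L),
               float64 = list(code = 64L, bits = 64L, what = "double", size = 8L))
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wi(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(35), con); wi(0L, 1L)             # unused + dim_info
  dims <- c(length(d), d, rep(1L, 7L - length(d)))
  wi(dims, 2L)                                   # dim[8]
  wf(c(0, 0, 0)); wi(c(0L, 0L), 2L)              # intent_p1-3, intent_code, datatype placeholder rewritten below
  # note: intent_p1..3 are floats (12 bytes), intent_code+datatype are shorts
  seek(con, 70L)
  wi(dt$code, 2L)                                # datatype
  wi(dt$bits, 2L)                                # bitpix
  wi(0L, 2L)                                     # slice_start
  wf(c(1, rep(voxel_size_mm, 3L), rep(1, 4L)))   # pixdim[8]
  wf(352)                                        # vox_offset
  wf(c(1, 0))                                    # scl_slope, scl_inter
  wi(0L, 2L); wi(0L, 1L); wi(0L, 1L)             # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                                 # cal_max, cal_min, slice_duration
  wf(0)                                          # toffset
  wi(c(0L, 0L), 4L)                              # glmax, glmin
  writeBin(raw(104L), con)                       # descrip[80] + aux_file[24]
  wi(c(0L, 0L), 2L)                              # qform_code, sform_code
  wf(rep(0, 18L))                                # quaternions + srow
  writeBin(raw(16L), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4L), con)                         # extension flag
  vals <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1L, 4L, endian = "little")
  if (hdr_size != 348L) stop("not a little-endian NIfTI-1 file: ", path)
  seek(con, 40L)
  dims <- readBin(con, "integer", 8L, 2L, endian = "little")
  seek(con, 70L)
  code <- readBin(con, "integer", 1L, 2L, endian = "little")
  seek(con, 76L)
  pixdim <- readBin(con, "double", 8L, 4L, endian = "little")
  vox_offset <- readBin(con, "double", 1L, 4L, endian = "little")
  scl <- readBin(con, "double", 2L, 4L, endian = "little")
  nd <- dims[1L]
  if (!nd %in% 3:4) stop("unsupported dimensionality: ", nd)
  d <- dims[2L:(1L + nd)]
  n <- prod(d)
  seek(con, vox_offset)
  vals <- switch(as.character(code),
                 `2` = readBin(con, "integer", n, 1L, signed = FALSE,
                               endian = "little"),
                 `4` = readBin(con, "integer", n, 2L, endian = "little"),
                 `8` = readBin(con, "integer", n, 4L, endian = "little"),
                 `16` = readBin(con, "double", n, 4L, endian = "little"),
                 `64` = readBin(con, "double", n, 8L, endian = "little"),
                 stop("unsupported NIfTI datatype code: ", code))
  if (!(scl[1L] %in% c(0, 1)) || scl[2L] != 0)
    vals <- vals * ifelse(scl[1L] == 0, 1, scl[1L]) + scl[2L]
  out <- array(vals, d)
  attr(out, "voxel_size_mm") <- pixdim[2L]
  out
}
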