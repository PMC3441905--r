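# Minimal NIfTI-1 single-file (.nii) reader/writer.  No NIfTI package is
# available in the supported dependency set, so the small subset needed
# here (uncompressed .nii, 2-D/3-D, common datatypes, pixdim, scl slope/
# intercept) is implemented directly against the NIfTI-1 header layout.
# In-memory convention: R arrays are [row(y), col(x), slice]; on disk the
# x dimension varies fastest, so axes are permuted on write/read.

NIFTI_DT <- list(uint8 = c(2L, 8L), int16 = c(4L, 16L), int32 = c(8L, 32L),
                 float32 = c(16L, 32L), float64 = c(64L, 64L))

pad_raw <- function(s, n) {
  r <- raw(n)
  b <- charToRaw(as.character(s))
  if (length(b) > 0) r[seq_len(min(length(b), n))] <- b[seq_len(min(length(b), n))]
  r
}

#' Write a matrix or 3-D array as a NIfTI-1 file
#'
#' @param data numeric matrix `[rows, cols]` or array `[rows, cols, n]`.
#' @param path output path (`.nii`, uncompressed).
#' @param pixdim voxel dimensions `(row mm, col mm, slice mm)`.
#' @param datatype `"float32"` (default), `"float64"`, `"int16"`,
#'   `"int32"` or `"uint8"`.
#' @param descrip short description stored in the header.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = c(1, 1, 1),
                        datatype = "float32", descrip = "ecvmap") {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L)
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(10 + 18 + 4 + 2 + 1 + 1), con)   # data_type..dim_info
  wi(c(3L, d[2], d[1], d[3], 1L, 1L, 1L, 1L), 2)  # dim: x=cols varies fastest
  wf(c(0, 0, 0)); wi(0L, 2)                     # intent
  wi(dt[1], 2); wi(dt[2], 2); wi(0L, 2)         # datatype, bitpix, slice_start
  wf(c(1, pixdim[2], pixdim[1], pixdim[3], 0, 0, 0, 0))  # pixdim
  wf(352); wf(1); wf(0)                         # vox_offset, scl_slope/inter
  wi(0L, 2); writeBin(raw(2), con)              # slice_end, slice/xyzt codes
  wf(c(0, 0, 0, 0))                             # cal_max/min, slice_dur, toffset
  wi(c(0L, 0L), 4)                              # glmax/glmin
  writeBin(pad_raw(descrip, 80), con)
  writeBin(raw(24), con)                        # aux_file
  wi(c(0L, 1L), 2)                              # qform_code, sform_code
  wf(rep(0, 6))                                 # quatern, qoffset
  wf(c(pixdim[2], 0, 0, 0))                     # srow_x
  wf(c(0, pixdim[1], 0, 0))                     # srow_y
  wf(c(0, 0, pixdim[3], 0))                     # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  writeBin(raw(4), con)                         # no extensions
  vec <- as.numeric(aperm(data, c(2, 1, 3)))
  if (datatype %in% c("uint8", "int16", "int32")) {
    writeBin(as.integer(round(vec)), con, size = dt[2] / 8, endian = "little")
  } else {
    writeBin(vec, con, size = dt[2] / 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()] (or compatible)
#'
#' Supports uncompressed single-file `.nii` with up to 3 dimensions and
#' datatypes uint8/int16/int32/float32/float64; scl_slope/scl_inter are
#' applied when set.
#'
#' @param path file path.
#' @return A list with `data` (array `[rows, cols, n]`) and `pixdim`
#'   `(row mm, col mm, slice mm)`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sz <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    seek(con, 0)
    sz <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path)
  }
  seek(con, 40)
  dims <- readBin(con, "integer", 8, size = 2, endian = endian)
  ndim <- dims[1]
  if (ndim < 2 || ndim > 3) stop("only 2-D/3-D NIfTI supported")
  d <- c(dims[2], dims[3], if (ndim >= 3) dims[4] else 1L)
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  seek(con, 76)
  pd <- readBin(con, "numeric", 8, size = 4, endian = endian)
  seek(con, 108)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  seek(con, 344)
  magic <- rawToChar(readBin(con, "raw", 3))
  if (!magic %in% c("n+1", "ni1")) stop("unrecognized NIfTI magic: ", magic)
  seek(con, max(vox_offset, 352))
  nvox <- prod(d)
  vec <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", nvox, size = 1, signed = FALSE,
                             endian = endian)),
    "4" = as.numeric(readBin(con, "integer", nvox, size = 2, endian = endian)),
    "8" = as.numeric(readBin(con, "integer", nvox, size = 4, endian = endian)),
    "16" = readBin(con, "numeric", nvox, size = 4, endian = endian),
    "64" = readBin(con, "numeric", nvox, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (length(vec) != nvox) stop("truncated NIfTI data in ", path)
  if (is.finite(slope) && slope != 0 && !(slope == 1 && inter == 0))
    vec <- vec * slope + inter
  data <- aperm(array(vec, dim = d), c(2, 1, 3))
  list(data = data, pixdim = c(pd[3], pd[2], pd[4]))
}
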