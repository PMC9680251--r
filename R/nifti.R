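## Minimal NIfTI-1 reader/writer.
##
## The pre-installed R stack has no NIfTI package, so the small subset of
## NIfTI-1 this pipeline needs is implemented directly: single-file .nii
## (optionally gzipped), little- or big-endian headers, datatypes uint8,
## int16, int32, float32, float64, no extensions, scl_slope/scl_inter
## applied on read. Spatial units are written as mm and temporal as s
## (xyzt_units = 10); pixdim[5] carries the frame interval.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

open_nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric array), `dim`, `pixdim` (full 8-vector
#'   as stored), `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- open_nii_con(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    if (.swap_int32(sizeof_hdr) == 348L) endian <- "big"
    else stop(sprintf("'%s' is not a NIfTI-1 file (sizeof_hdr = %d)",
                      path, sizeof_hdr))
  }
  readBin(con, "raw", 36)                                   # filler to dim
  dm <- readBin(con, "integer", 8, size = 2, endian = endian)
  readBin(con, "raw", 14)                                   # intent_*
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "integer", 1, size = 2, endian = endian)     # bitpix
  readBin(con, "raw", 2)                                    # slice_start
  pixdim <- readBin(con, "double", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, size = 4, endian = endian)
  readBin(con, "raw", 348 - 120)                            # rest of header
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt))
    stop(sprintf("unsupported NIfTI datatype %d in '%s'", datatype, path))
  ndim <- dm[1]
  if (ndim < 1L || ndim > 7L) stop(sprintf("corrupt NIfTI dim[0] = %d", ndim))
  shape <- pmax(dm[2:(1 + ndim)], 1L)
  nvox <- prod(shape)
  skip <- max(vox_offset, 348) - 348
  if (skip > 0) readBin(con, "raw", skip)
  data <- readBin(con, dt$what, nvox, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(data) < nvox)
    stop(sprintf("'%s' truncated: expected %d voxels, read %d",
                 path, nvox, length(data)))
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(as.double(data), dim = shape),
       dim = shape, pixdim = pixdim, datatype = datatype)
}

.swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4, endian = "little")
  readBin(rev(b), "integer", 1, size = 4, endian = "little")
}

#' Write a NIfTI-1 volume
#'
#' @param data numeric array, 3D or 4D.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param pixdim voxel spacing in mm (length 3) optionally followed by the
#'   frame interval in seconds (length 4).
#' @param datatype NIfTI datatype code: 16 (float32, default), 64
#'   (float64), 2 (uint8), 4 (int16), 8 (int32).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = c(1, 1, 1), datatype = 16L) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L) stop("only 3D or 4D volumes are written")
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop(sprintf("unsupported datatype %d", datatype))
  dm <- integer(8); dm[1] <- nd; dm[2:(1 + nd)] <- dim(data)
  dm[(2 + nd):8] <- 1L
  pd <- numeric(8); pd[1] <- 1
  pd[2:(1 + length(pixdim))] <- pixdim

  con <- open_nii_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                      # sizeof_hdr
  wraw(36)                         # data_type..dim_info
  wi(dm, 2)                        # dim
  wraw(12)                         # intent_p1..p3
  wi(0L, 2)                        # intent_code
  wi(datatype, 2)                  # datatype
  wi(dt$bitpix, 2)                 # bitpix
  wi(0L, 2)                        # slice_start
  wf(pd)                           # pixdim
  wf(352)                          # vox_offset
  wf(1); wf(0)                     # scl_slope, scl_inter
  wi(0L, 2); wraw(1)               # slice_end, slice_code
  writeBin(as.raw(10L), con)       # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0))                # cal_max..toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  wraw(80 + 24)                    # descrip, aux_file
  wi(c(0L, 1L), 2)                 # qform_code, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))          # quatern/qoffset
  wf(c(pd[2], 0, 0, 0))            # srow_x
  wf(c(0, pd[3], 0, 0))            # srow_y
  wf(c(0, 0, pd[4], 0))            # srow_z
  wraw(16)                         # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(as.raw(0L), con)        # magic terminator
  wraw(4)                          # extension flag
  if (dt$what == "double") {
    writeBin(as.numeric(data), con, size = dt$size, endian = "little")
  } else {
    storage.mode(data) <- "integer"
    writeBin(as.vector(data), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
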