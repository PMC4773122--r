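# Minimal NIfTI-1 (.nii, single file) reader/writer.
#
# No NIfTI package is available in the supported dependency set, so the
# subset of the format this package needs is implemented directly against
# the NIfTI-1 header definition: 3D/4D volumes, sform affine, the common
# numeric datatypes, both endiannesses on read, float32 little-endian on
# write.  The affine maps 0-based voxel indices (voxel centers) to world mm.

NIFTI_DATATYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)    # float64
)

#' Write a 3D or 4D array as a NIfTI-1 volume
#'
#' @param img numeric array, 3 or 4 dimensions.
#' @param path output file, conventionally ending in `.nii`.
#' @param affine 4x4 matrix mapping 0-based voxel indices to world mm.
#' @param datatype `"float32"` (default) or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, affine = diag(4), datatype = "float32") {
  nd <- length(dim(img))
  if (!nd %in% c(3L, 4L)) stop("img must be a 3D or 4D array")
  if (!is.matrix(affine) || !all(dim(affine) == c(4, 4)))
    stop("affine must be a 4x4 matrix")
  dt_code <- switch(datatype, float32 = 16L, float64 = 64L,
                    stop("unsupported write datatype: ", datatype))
  dt_size <- if (dt_code == 16L) 4L else 8L

  dims <- dim(img)
  dim8 <- integer(8); dim8[1] <- nd; dim8[2:(1 + nd)] <- dims
  dim8[dim8 == 0L] <- 1L
  # voxel sizes from affine column norms
  pixdim <- numeric(8)
  pixdim[1] <- 1
  pixdim[2:4] <- sqrt(colSums(affine[1:3, 1:3]^2))
  pixdim[5] <- 1

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wc <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw[seq_len(min(length(raw), len))],
               raw(len - min(length(raw), len))), con)
  }

  wi(348L, 4)                 # sizeof_hdr
  wc("", 10); wc("", 18)      # data_type, db_name (unused)
  wi(0L, 4); wi(0L, 2); wc("r", 1); wc("", 1)  # extents, session_error, regular, dim_info
  wi(dim8, 2)
  wf(c(0, 0, 0)); wi(0L, 2)   # intent_p1-3, intent_code
  wi(dt_code, 2); wi(8L * dt_size, 2)  # datatype, bitpix
  wi(0L, 2)                   # slice_start
  wf(pixdim)
  wf(352)                     # vox_offset
  wf(1); wf(0)                # scl_slope, scl_inter
  wi(0L, 2); wc("", 1); wc(rawToChar(as.raw(10L)), 1)  # slice_end, slice_code, xyzt_units (mm|s)
  wf(c(0, 0)); wf(0); wf(0)   # cal_max/min, slice_duration, toffset
  wi(c(0L, 0L), 4)            # glmax, glmin
  wc("dwiphantom", 80); wc("", 24)  # descrip, aux_file
  wi(0L, 2); wi(1L, 2)        # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0)); wf(c(0, 0, 0))    # quatern, qoffset
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])
  wc("", 16)
  wc("n+1", 4)
  writeBin(raw(4), con)       # no extensions

  writeBin(as.double(img), con, size = dt_size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` file.
#' @return list with `img` (array), `affine` (4x4), `voxel_size_mm`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  sz_le <- readBin(hdr[1:4], "integer", 1, 4, endian = "little")
  endian <- if (sz_le == 348L) "little" else "big"
  sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
  if (sz != 348L) stop("not a NIfTI-1 file (sizeof_hdr = ", sz_le, "): ", path)
  ri <- function(off, n, size) readBin(hdr[(off + 1):(off + n * size)],
                                       "integer", n, size, endian = endian)
  rf <- function(off, n, size = 4L) readBin(hdr[(off + 1):(off + n * size)],
                                            "double", n, size, endian = endian)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("bad NIfTI magic string '", magic, "' in ", path)
  dim8 <- ri(40, 8, 2)
  nd <- dim8[1]
  if (!nd %in% 1:4) stop("unsupported NIfTI dimensionality: ", nd)
  dims <- pmax(dim8[2:(1 + nd)], 1L)
  dt_code <- ri(70, 1, 2)
  spec <- NIFTI_DATATYPES[[as.character(dt_code)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", dt_code)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108, 1)
  scl_slope <- rf(112, 1); scl_inter <- rf(116, 1)
  sform_code <- ri(254, 1, 2)
  if (sform_code > 0L) {
    affine <- rbind(matrix(rf(280, 12), 3, 4, byrow = TRUE), c(0, 0, 0, 1))
  } else {
    affine <- diag(4)
    diag(affine)[1:3] <- pixdim[2:4]
  }
  seek(con, where = vox_offset, origin = "start")
  n <- prod(dims)
  vals <- readBin(con, spec$what, n, size = spec$size, signed = spec$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  img <- array(vals, dim = dims)
  list(img = img, affine = affine,
       voxel_size_mm = sqrt(colSums(affine[1:3, 1:3]^2)))
}
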