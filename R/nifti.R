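## Minimal NIfTI-1 reader/writer. No NIfTI package is available in the
## target environment, so the package carries its own codec for the subset
## it needs: single 3-D image, sform affine, little-endian, datatypes
## uint8 / int16 / int32 / float32 / float64, optional gzip (.nii.gz).

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L)
NIFTI_BITPIX <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)

nii_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a volume to a NIfTI-1 file
#'
#' Writes a single-frame NIfTI-1 (.nii or .nii.gz) with the volume's affine
#' stored as the sform (sform_code = 2, aligned) and qform disabled.
#'
#' @param vol `volume3d`
#' @param path output path; `.gz` suffix triggers gzip compression
#' @param datatype one of "uint8", "int16", "int32", "float32", "float64"
#' @return `path`, invisibly
#' @export
write_nifti <- function(vol, path, datatype = "float32") {
  stopifnot_msg(inherits(vol, "volume3d"), "vol must be a volume3d")
  dt <- NIFTI_DT[[datatype]]
  stopifnot_msg(!is.null(dt), "unsupported datatype '%s'", datatype)
  d <- dim(vol$voxels)
  con <- nii_connection(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                      # sizeof_hdr
  w_raw(36)                        # data_type[10], db_name[18], extents, session_error, regular, dim_info
  w_i16(c(3L, d, 1L, 1L, 1L, 1L))  # dim[8]
  w_f32(c(0, 0, 0))                # intent_p1..p3
  w_i16(0L)                        # intent_code
  w_i16(dt)                        # datatype
  w_i16(NIFTI_BITPIX[[as.character(dt)]])  # bitpix
  w_i16(0L)                        # slice_start
  w_f32(c(1, vol$voxel_mm, 0, 0, 0, 0))    # pixdim[8] (qfac = 1)
  w_f32(352)                       # vox_offset
  w_f32(c(1, 0))                   # scl_slope, scl_inter
  w_i16(0L)                        # slice_end
  w_raw(2)                         # slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  w_raw(80 + 24)                   # descrip, aux_file
  w_i16(c(0L, 2L))                 # qform_code = 0, sform_code = 2
  w_f32(rep(0, 6))                 # quatern b,c,d + qoffset x,y,z
  w_f32(t(vol$affine[1:3, ]))      # srow_x, srow_y, srow_z
  w_raw(16)                        # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  w_raw(1)                         # magic terminator
  w_raw(4)                         # pad to vox_offset 352

  x <- as.vector(vol$voxels)
  if (datatype %in% c("uint8", "int16", "int32")) {
    writeBin(as.integer(round(x)), con,
             size = NIFTI_BITPIX[[as.character(dt)]] / 8, endian = "little")
  } else {
    writeBin(as.double(x), con, size = NIFTI_BITPIX[[as.character(dt)]] / 8,
             endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file into a volume
#'
#' Supports 3-D single-frame images with the datatypes written by
#' [write_nifti()]; honors the sform when present (falling back to a pixdim
#' diagonal affine) and applies scl_slope / scl_inter scaling.
#'
#' @param path path to a `.nii` or `.nii.gz` file
#' @return `volume3d`
#' @export
read_nifti <- function(path) {
  con <- nii_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  stopifnot_msg(length(hdr) == 348, "truncated NIfTI header in %s", path)
  endian <- "little"
  rd <- function(what, n, size, off) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = !(what == "integer" && size == 1))
  }
  if (rd("integer", 1, 4, 0) != 348L) {
    endian <- "big"
    stopifnot_msg(rd("integer", 1, 4, 0) == 348L, "not a NIfTI-1 file: %s", path)
  }
  dim8 <- rd("integer", 8, 2, 40)
  stopifnot_msg(dim8[1] >= 3 && all(dim8[5:8] <= 1 | dim8[1] == 3),
                "only 3-D NIfTI volumes are supported")
  d <- dim8[2:4]
  datatype <- rd("integer", 1, 2, 70)
  pixdim <- rd("numeric", 8, 4, 76)
  vox_offset <- rd("numeric", 1, 4, 108)
  scl_slope <- rd("numeric", 1, 4, 112)
  scl_inter <- rd("numeric", 1, 4, 116)
  sform_code <- rd("integer", 1, 2, 254)
  srow <- matrix(rd("numeric", 12, 4, 280), 3, 4, byrow = TRUE)
  n <- prod(d)
  seek(con, where = vox_offset, origin = "start")
  vals <- switch(as.character(datatype),
    `2`  = readBin(con, "integer", n, size = 1, signed = FALSE, endian = endian),
    `4`  = readBin(con, "integer", n, size = 2, endian = endian),
    `8`  = readBin(con, "integer", n, size = 4, endian = endian),
    `16` = readBin(con, "numeric", n, size = 4, endian = endian),
    `64` = readBin(con, "numeric", n, size = 8, endian = endian),
    abort("unsupported NIfTI datatype %d", datatype))
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  A <- diag(4)
  if (sform_code > 0) {
    A[1:3, ] <- srow
  } else {
    A[1:3, 1:3] <- diag(pixdim[2:4], 3, 3)
  }
  volume3d(array(as.double(vals), d), affine = A)
}
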