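# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# Supports 3D and 4D volumes, float32/float64/int16/uint8 storage, the
# sform affine (srow_*), and pixdim spacing. No R NIfTI package is assumed.

#' Write a 3D or 4D array as a NIfTI-1 file
#'
#' @param data numeric array (3D, or 4D with channels last).
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param spacing voxel spacing in mm (length 3).
#' @param affine optional 4x4 grid-to-world matrix; default diagonal from
#'   `spacing`.
#' @param datatype `"float32"` (default), `"int16"` or `"uint8"`.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), affine = NULL,
                        datatype = "float32") {
  nd <- length(dim(data))
  stopifnot(nd %in% c(3L, 4L))
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  dt <- switch(datatype, float32 = c(16L, 32L), int16 = c(4L, 16L),
               uint8 = c(2L, 8L), stop("unsupported datatype"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  dims <- integer(8); dims[1] <- nd
  dims[2:(1 + nd)] <- dim(data)
  dims[(2 + nd):8] <- 1L
  writeBin(348L, con, size = 4, endian = "little")          # sizeof_hdr
  writeBin(raw(36), con)                                     # unused
  writeBin(as.integer(dims), con, size = 2, endian = "little")
  writeBin(raw(14), con)                                     # intent etc
  writeBin(as.integer(dt[1]), con, size = 2, endian = "little")   # datatype
  writeBin(as.integer(dt[2]), con, size = 2, endian = "little")   # bitpix
  writeBin(0L, con, size = 2, endian = "little")             # slice_start
  pixdim <- numeric(8); pixdim[1] <- 1
  pixdim[2:4] <- spacing; pixdim[5:8] <- c(1, 0, 0, 0)
  writeBin(pixdim, con, size = 4, endian = "little")
  writeBin(352, con, size = 4, endian = "little")            # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")        # scl_slope/inter
  writeBin(raw(8), con)                                      # slice_end..cal
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")     # cal_min, slice_dur, toffset
  writeBin(c(0L, 0L), con, size = 4, endian = "little")      # glmax/glmin
  writeBin(charToRaw(formatC("", width = 80)), con)          # descrip
  writeBin(charToRaw(formatC("", width = 24)), con)          # aux_file
  writeBin(c(0L, 1L), con, size = 2, endian = "little")      # qform=0, sform=1
  writeBin(numeric(3), con, size = 4, endian = "little")     # quatern_b/c/d
  writeBin(numeric(3), con, size = 4, endian = "little")     # qoffset_x/y/z
  writeBin(as.numeric(t(affine[1:3, ])), con, size = 4, endian = "little")
  writeBin(charToRaw(formatC("", width = 16)), con)          # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)              # magic
  writeBin(raw(4), con)                                      # extension flag
  vals <- as.numeric(data)
  if (datatype == "float32") writeBin(vals, con, size = 4, endian = "little")
  else writeBin(as.integer(round(vals)), con, size = dt[2] / 8, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()] (or compatible)
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (array), `spacing`, `affine`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  sz <- readBin(hdr[1:4], "integer", 1, size = 4, endian = "little")
  if (sz != 348) stop("not a NIfTI-1 file (or wrong endianness): ", path)
  dims <- readBin(hdr[41:56], "integer", 8, size = 2, endian = "little")
  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  datatype <- readBin(hdr[71:72], "integer", 1, size = 2, endian = "little")
  pixdim <- readBin(hdr[77:108], "numeric", 8, size = 4, endian = "little")
  vox_offset <- readBin(hdr[109:112], "numeric", 1, size = 4, endian = "little")
  srow <- readBin(hdr[281:328], "numeric", 12, size = 4, endian = "little")
  affine <- rbind(matrix(srow, 3, 4, byrow = TRUE), c(0, 0, 0, 1))
  n <- prod(shape)
  # skip to vox_offset without seek() (unreliable on gzip connections)
  skip <- round(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  data <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4" = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "8" = as.numeric(readBin(con, "integer", n, size = 4, endian = "little")),
    "16" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code ", datatype))
  dim(data) <- shape
  list(data = data, spacing = pixdim[2:4], affine = affine)
}
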