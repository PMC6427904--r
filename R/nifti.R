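# Minimal NIfTI-1 and MetaImage I/O.
#
# Only the subset needed for co-registered scalar volumes is supported: 3D
# grids, little- or big-endian, the common scalar datatypes, gzip transparent
# for .nii.gz. Orientation (qform/sform) is carried through as an opaque
# attribute; all modalities of a subject are assumed to live on one voxel grid.

.NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2, signed = FALSE)   # uint16
)

.open_vol_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads a scalar 3D volume from a `.nii` or `.nii.gz` file. Data slope and
#' intercept scaling (`scl_slope`, `scl_inter`) are applied when present.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A numeric 3D array with attributes `pixdim` (voxel spacing) and
#'   `nifti_header` (the raw header fields kept for round-tripping).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- .open_vol_con(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    if (.swap_int4(sizeof_hdr) != 348L)
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  readBin(con, "raw", 36L)                                   # unused header pad
  dim <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                                   # intent fields
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  spec <- .NIFTI_DT[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code: ", datatype)
  ndim <- dim[1]
  if (ndim < 3L) stop("expected a 3D volume, got ", ndim, "D")
  shape <- dim[2:4]
  if (ndim > 3L && any(dim[5:(1 + ndim)] > 1L))
    stop("4D+ volumes are not supported")
  # skip the remainder of the header + extension up to vox_offset
  consumed <- 40L + 16L + 14L + 2L + 2L + 2L + 32L + 4L + 4L + 4L
  readBin(con, "raw", round(vox_offset) - consumed)
  n <- prod(shape)
  vals <- readBin(con, spec$what, n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  vol <- array(vals, dim = shape)
  attr(vol, "pixdim") <- pixdim[2:4]
  vol
}

.swap_int4 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  readBin(rev(b), "integer", 1L, size = 4L, endian = "little")
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D array to `.nii` or `.nii.gz` (gzip chosen from the extension).
#' `datatype` "float64" round-trips doubles bit-exactly; "int16"/"uint8" store
#' integer label volumes compactly.
#'
#' @param vol A numeric or integer 3D array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype One of "float64", "float32", "int16", "int32", "uint8".
#' @param pixdim Voxel spacing, length 3 (default 1 mm isotropic).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = c("float64", "float32", "int16",
                                                "int32", "uint8"),
                        pixdim = c(1, 1, 1)) {
  datatype <- match.arg(datatype)
  stopifnot(length(dim(vol)) == 3L)
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L)
  size <- switch(datatype, uint8 = 1L, int16 = 2L, int32 = 4L,
                 float32 = 4L, float64 = 8L)
  con <- .open_vol_con(path, "wb")
  on.exit(close(con))
  w_i4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f4 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i4(348L); w_raw(36L)
  w_i2(c(3L, dim(vol), 1L, 1L, 1L, 1L))
  w_raw(14L)
  w_i2(code); w_i2(8L * size); w_i2(0L)
  w_f4(c(0, pixdim, rep(0, 4)))
  w_f4(352); w_f4(1); w_f4(0)                         # vox_offset, scl
  w_raw(4L)                                           # slice_end/code, xyzt_units
  w_f4(rep(0, 6))                                     # cal_max..toffset, glmax/min
  w_raw(80L + 24L)                                    # descrip + aux_file
  w_i2(c(0L, 0L))                                     # qform/sform codes
  w_f4(rep(0, 18))                                    # quatern + srows
  w_raw(16L)                                          # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL); w_raw(1L)
  w_raw(4L)                                           # extension flag
  storage <- if (size <= 4L && code != 16L) "integer" else "double"
  if (storage == "integer")
    writeBin(as.integer(round(as.vector(vol))), con, size = size, endian = "little")
  else
    writeBin(as.double(as.vector(vol)), con, size = size, endian = "little")
  invisible(path)
}

.MHA_TYPES <- c(MET_UCHAR = "uint8", MET_SHORT = "int16", MET_INT = "int32",
                MET_FLOAT = "float32", MET_DOUBLE = "float64")

#' Read a MetaImage (.mha) volume
#'
#' Supports single-file MetaImage volumes (`ElementDataFile = LOCAL`),
#' uncompressed, little-endian, scalar element types.
#'
#' @param path Path to an `.mha` file.
#' @return A numeric 3D array with a `pixdim` attribute (ElementSpacing).
#' @export
read_mha <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- .read_header_line(con)
    if (is.null(line)) stop("malformed MetaImage header in ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  if (toupper(hdr$ElementDataFile) != "LOCAL")
    stop("only ElementDataFile = LOCAL .mha files are supported")
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("compressed MetaImage data is not supported")
  shape <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(shape) != 3L) stop("expected NDims = 3 MetaImage")
  type <- .MHA_TYPES[[hdr$ElementType]]
  if (is.null(type)) stop("unsupported ElementType: ", hdr$ElementType)
  endian <- "little"
  if (!is.null(hdr$ElementByteOrderMSB) &&
      toupper(hdr$ElementByteOrderMSB) == "TRUE") endian <- "big"
  n <- prod(shape)
  vals <- switch(type,
    uint8   = readBin(con, "integer", n, size = 1L, signed = FALSE, endian = endian),
    int16   = readBin(con, "integer", n, size = 2L, endian = endian),
    int32   = readBin(con, "integer", n, size = 4L, endian = endian),
    float32 = readBin(con, "double",  n, size = 4L, endian = endian),
    float64 = readBin(con, "double",  n, size = 8L, endian = endian))
  if (length(vals) != n) stop("truncated MetaImage data in ", path)
  vol <- array(as.double(vals), dim = shape)
  if (!is.null(hdr$ElementSpacing))
    attr(vol, "pixdim") <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  vol
}

.read_header_line <- function(con) {
  chars <- character(0)
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) return(if (length(chars)) paste(chars, collapse = "") else NULL)
    if (ch == "\n") return(paste(chars, collapse = ""))
    if (ch != "\r") chars <- c(chars, ch)
  }
}

#' Write a MetaImage (.mha) volume
#'
#' @inheritParams write_nifti
#' @param path Output path ending in `.mha`.
#' @return `path`, invisibly.
#' @export
write_mha <- function(vol, path, datatype = c("float64", "float32", "int16",
                                              "int32", "uint8"),
                      pixdim = c(1, 1, 1)) {
  datatype <- match.arg(datatype)
  stopifnot(length(dim(vol)) == 3L)
  met <- names(.MHA_TYPES)[match(datatype, .MHA_TYPES)]
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    "ObjectType = Image\n",
    "NDims = 3\n",
    "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    "CompressedData = False\n",
    "DimSize = ", paste(dim(vol), collapse = " "), "\n",
    "ElementSpacing = ", paste(pixdim, collapse = " "), "\n",
    "ElementType = ", met, "\n",
    "ElementDataFile = LOCAL\n")
  writeChar(hdr, con, eos = NULL)
  size <- switch(datatype, uint8 = 1L, int16 = 2L, int32 = 4L,
                 float32 = 4L, float64 = 8L)
  if (datatype %in% c("float32", "float64"))
    writeBin(as.double(as.vector(vol)), con, size = size, endian = "little")
  else
    writeBin(as.integer(round(as.vector(vol))), con, size = size, endian = "little")
  invisible(path)
}

#' Read a volume, dispatching on extension
#'
#' @param path Path ending in `.nii`, `.nii.gz`, or `.mha`.
#' @return A numeric 3D array.
#' @export
read_volume <- function(path) {
  if (grepl("\\.mha$", path)) read_mha(path) else read_nifti(path)
}

#' Write a volume, dispatching on extension
#'
#' @inheritParams write_nifti
#' @export
write_volume <- function(vol, path, datatype = "float64", pixdim = c(1, 1, 1)) {
  if (grepl("\\.mha$", path)) write_mha(vol, path, datatype, pixdim)
  else write_nifti(vol, path, datatype, pixdim)
}
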