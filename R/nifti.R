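#' @title Minimal NIfTI-1 reader/writer
#' @description Single-file NIfTI-1 (.nii, .nii.gz) support for 3D scalar
#' volumes. Only the header fields this package needs are interpreted:
#' `dim`, `datatype`, `bitpix`, `pixdim`, `vox_offset`, `scl_slope`,
#' `scl_inter` and the magic. Both endiannesses are handled on read; files
#' are written little-endian with a 348-byte header and data at offset 352.
#' @name nifti-io
#' @keywords internal
NULL

.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

#' Read a 3D NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (3D numeric array), `spacing` (dx, dy, dz in mm)
#'   and `dim`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", n = 1L, size = 4L, endian = endian)
  if (!identical(sizeof_hdr, 348L)) {
    swapped <- readBin(writeBin(sizeof_hdr, raw(), size = 4L,
                                endian = "little"),
                       "integer", size = 4L, endian = "big")
    if (identical(swapped, 348L)) {
      endian <- "big"
    } else {
      stop("corrupt NIfTI header (sizeof_hdr = ", sizeof_hdr, "): ", path)
    }
  }
  readBin(con, "raw", n = 36L)                       # skip to offset 40
  dims <- readBin(con, "integer", n = 8L, size = 2L, endian = endian)
  readBin(con, "raw", n = 14L)                       # intent fields
  datatype <- readBin(con, "integer", n = 1L, size = 2L, endian = endian)
  readBin(con, "integer", n = 1L, size = 2L, endian = endian)  # bitpix
  readBin(con, "integer", n = 1L, size = 2L, endian = endian)  # slice_start
  pixdim <- readBin(con, "double", n = 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", n = 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", n = 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", n = 1L, size = 4L, endian = endian)
  # consumed so far: 120 bytes; magic sits at 344
  readBin(con, "raw", n = 224L)
  magic <- rawToChar(readBin(con, "raw", n = 3L))
  readBin(con, "raw", n = 1L)
  if (!magic %in% c("n+1", "ni1")) {
    stop("corrupt NIfTI header (bad magic): ", path)
  }
  ndim <- dims[1L]
  shape <- dims[seq(2L, 1L + max(ndim, 1L))]
  if (ndim == 4L && shape[4L] == 1L) { ndim <- 3L; shape <- shape[1:3] }
  if (ndim != 3L) {
    stop("expected 3D volume, got ", ndim, "D in ", path)
  }
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n_vox <- prod(shape)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) != n_vox) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  spacing <- abs(pixdim[2:4])
  spacing[spacing == 0] <- 1
  list(data = array(vals, dim = shape), spacing = spacing, dim = shape)
}

#' Write a 3D array as NIfTI-1
#'
#' @param data 3D numeric array.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @param datatype NIfTI datatype code: 64 (float64, default) or 2 (uint8,
#'   used for masks).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), datatype = 64L) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L,
            all(spacing > 0))
  datatype <- as.integer(datatype)
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported write datatype ", datatype)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  en <- "little"
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = en)
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = en)
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = en)
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                                  # sizeof_hdr
  w_raw(36L)                                   # data_type..dim_info
  w_i16(c(3L, dim(data), 1L, 1L, 1L, 1L))      # dim[8]
  w_raw(14L)                                   # intent_p1..intent_code
  w_i16(datatype)                              # datatype
  w_i16(dt$size * 8L)                          # bitpix
  w_i16(0L)                                    # slice_start
  w_f32(c(0, spacing, 0, 0, 0, 0))             # pixdim[8]
  w_f32(352)                                   # vox_offset
  w_f32(1); w_f32(0)                           # scl_slope, scl_inter
  w_raw(224L)                                  # slice_end .. srow/intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  w_raw(4L)                                    # extension flag
  vals <- as.vector(data)
  if (dt$what == "integer") {
    vals <- as.integer(round(vals))
    writeBin(vals, con, size = dt$size, endian = en)
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = en)
  }
  invisible(path)
}
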