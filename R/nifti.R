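# Minimal single-file NIfTI-1 input/output for 3D volumes, written against
# the nifti1.h layout (348-byte header, magic "n+1", data at vox_offset).
# Deliberately small: 3D, scalar datatypes, diagonal sform built from the
# voxel size unless an affine is supplied. Gzipped files are handled
# through base R connections.

.nifti_dtypes <- list(
  "2" = list(what = "integer", size = 1L, signed = FALSE),   # uint8
  "4" = list(what = "integer", size = 2L, signed = TRUE),    # int16
  "8" = list(what = "integer", size = 4L, signed = TRUE),    # int32
  "16" = list(what = "double", size = 4L, signed = TRUE),    # float32
  "64" = list(what = "double", size = 8L, signed = TRUE)     # float64
)

.nifti_conn <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D volume as NIfTI-1
#'
#' @param img 3D numeric array.
#' @param path Output path; `.nii` or `.nii.gz`.
#' @param voxel_size Voxel edge lengths in mm, length 3.
#' @param descrip Free-text description (at most 79 bytes; units of the
#'   map are recorded here, NIfTI headers carry no formal unit field).
#' @param datatype `"float64"` (default, lossless for R doubles) or
#'   `"float32"`.
#' @param affine Optional 3 x 4 voxel-to-world matrix for the sform;
#'   default: diagonal of `voxel_size`.
#' @return The path, invisibly.
#' @export
write_nifti <- function(img, path, voxel_size = c(1, 1, 1), descrip = "",
                        datatype = c("float64", "float32"),
                        affine = NULL) {
  datatype <- match.arg(datatype)
  dm <- dim(img)
  if (is.null(dm) || length(dm) != 3L)
    stop("'img' must be a 3D array", call. = FALSE)
  code <- if (datatype == "float64") 64L else 16L
  bitpix <- if (datatype == "float64") 64L else 32L
  if (is.null(affine))
    affine <- cbind(diag(voxel_size), c(0, 0, 0))
  con <- .nifti_conn(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wc <- function(s, n) {
    raw <- charToRaw(as.character(s)[1])
    if (length(raw) >= n) raw <- raw[seq_len(n - 1L)]
    writeBin(c(raw, raw(n - length(raw))), con)
  }
  wi(348L, 4)                      # sizeof_hdr
  wc("", 10); wc("", 18)           # data_type, db_name (unused)
  wi(0L, 4); wi(0L, 2); wc("r", 1) # extents, session_error, regular
  wc("", 1)                        # dim_info
  wi(c(3L, dm, 1L, 1L, 1L, 1L), 2) # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)        # intent_p1..p3, intent_code
  wi(code, 2); wi(bitpix, 2); wi(0L, 2)  # datatype, bitpix, slice_start
  wf(c(1, voxel_size, 0, 0, 0, 0)) # pixdim[8] (qfac = 1)
  wf(352); wf(0); wf(0)            # vox_offset, scl_slope = 0, scl_inter
  wi(0L, 2); wc("", 1)             # slice_end, slice_code
  wi(10L, 1)                       # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_dur, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  wc(descrip, 80); wc("", 24)      # descrip, aux_file
  wi(0L, 2); wi(1L, 2)             # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))          # quatern b/c/d, qoffset x/y/z
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])
  wc("", 16)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4L), con)           # extension flag: none
  writeBin(as.numeric(img), con, size = bitpix / 8L, endian = "little")
  invisible(path)
}

#' Read a 3D NIfTI-1 volume
#'
#' Supports single-file `.nii`/`.nii.gz` with scalar datatypes (uint8,
#' int16, int32, float32, float64); `scl_slope`/`scl_inter` are applied
#' when set.
#'
#' @param path File path.
#' @return A 3D array with attributes `voxel_size`, `descrip` and
#'   `affine` (3 x 4 sform, or `NULL` when absent).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- .nifti_conn(path, "rb")
  on.exit(close(con))
  ri <- function(n, size, signed = TRUE)
    readBin(con, "integer", n = n, size = size, signed = signed,
            endian = "little")
  rf <- function(n) readBin(con, "double", n = n, size = 4L,
                            endian = "little")
  hdr <- ri(1, 4)
  if (!identical(hdr, 348L))
    stop("not a little-endian NIfTI-1 file: ", path, call. = FALSE)
  readBin(con, "raw", n = 36L)           # skip to dim
  dims <- ri(8, 2)
  if (dims[1] < 3L)
    stop("expected a 3D volume in ", path, call. = FALSE)
  if (dims[1] > 3L && any(dims[5:8][seq_len(dims[1] - 3L)] > 1L))
    stop("only 3D volumes are supported: ", path, call. = FALSE)
  dm <- dims[2:4]
  rf(3); ri(1, 2)                        # intent
  dtype <- ri(1, 2); ri(1, 2); ri(1, 2)  # datatype, bitpix, slice_start
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  ri(1, 2); readBin(con, "raw", n = 2L)  # slice_end, slice_code, units
  rf(4); ri(2, 4)                        # cal/slice/toffset, glmax/glmin
  descrip <- readBin(con, "raw", n = 80L)
  nz <- which(descrip != 0)
  descrip <- rawToChar(descrip[seq_len(if (length(nz)) max(nz) else 0L)])
  readBin(con, "raw", n = 24L)           # aux_file
  ri(1, 2)                               # qform_code
  sform_code <- ri(1, 2)
  rf(6)                                  # quaternion fields
  srow <- rbind(rf(4), rf(4), rf(4))
  readBin(con, "raw", n = 16L)           # intent_name
  magic <- rawToChar(readBin(con, "raw", n = 4L)[1:3])
  if (!magic %in% c("n+1", "ni1"))
    stop("bad NIfTI magic in ", path, call. = FALSE)
  dt <- .nifti_dtypes[[as.character(dtype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype code ", dtype, " in ", path,
         call. = FALSE)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(dm)
  v <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
               endian = "little")
  if (length(v) < n)
    stop("truncated NIfTI data in ", path, call. = FALSE)
  v <- as.numeric(v)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  out <- array(v, dm)
  attr(out, "voxel_size") <- pixdim[2:4]
  attr(out, "descrip") <- descrip
  attr(out, "affine") <- if (sform_code > 0L) srow else NULL
  out
}
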