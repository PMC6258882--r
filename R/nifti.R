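# Minimal single-file NIfTI-1 (.nii / .nii.gz) codec.
#
# Only what the pipeline needs: 3D/4D numeric volumes, little-endian,
# common datatypes, sform affine. Written because no NIfTI reader is
# available in the target R library set; not a general-purpose
# implementation (no .hdr/.img pairs, no extensions, no qform quaternion
# decoding beyond pass-through).

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)    # float64
)

nifti_con <- function(path, mode) {
  # gzfile transparently reads plain files too
  if (mode == "rb") gzfile(path, "rb")
  else if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}

#' Write a 3D/4D array as NIfTI-1
#'
#' Writes a single-file little-endian NIfTI-1 volume (gzipped when the
#' path ends in `.gz`). Data are stored as float64 so R doubles round-trip
#' bit-exactly; the affine goes into the sform rows (code 1).
#'
#' @param data 3D or 4D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-world matrix (default identity).
#' @param pixdim Voxel sizes, one per data dimension (default 1).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4), pixdim = NULL) {
  nd <- length(dim(data))
  if (!(nd %in% c(3L, 4L))) stop("data must be 3D or 4D", call. = FALSE)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (is.null(pixdim)) pixdim <- rep(1, nd)
  stopifnot(length(pixdim) == nd)
  dims <- integer(8); dims[1] <- nd; dims[1 + seq_len(nd)] <- dim(data)
  dims[dims == 0L] <- 1L
  pd <- numeric(8); pd[1 + seq_len(nd)] <- pixdim

  con <- nifti_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wc <- function(s, len) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(len - length(raw_s))), con)
  }
  wi(348L, 4)                      # sizeof_hdr
  writeBin(raw(36), con)           # data_type..dim_info (unused)
  wi(dims, 2)                      # dim[8]
  wf(c(0, 0, 0))                   # intent_p1..p3
  wi(0L, 2)                        # intent_code
  wi(64L, 2)                       # datatype = float64
  wi(64L, 2)                       # bitpix
  wi(0L, 2)                        # slice_start
  wf(pd)                           # pixdim[8]
  wf(352)                          # vox_offset
  wf(1); wf(0)                     # scl_slope, scl_inter
  wi(0L, 2)                        # slice_end
  writeBin(as.raw(c(0L, 10L)), con)  # slice_code, xyzt_units (mm | s)
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  wc("mwfpipe", 80)                # descrip
  wc("", 24)                       # aux_file
  wi(0L, 2); wi(1L, 2)             # qform_code = 0, sform_code = 1
  wf(numeric(6))                   # quatern_b..qoffset_z
  wf(t(affine[1:3, ]))             # srow_x, srow_y, srow_z
  wc("", 16)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  writeBin(raw(4), con)            # no extensions
  writeBin(as.numeric(data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return List: `data` (array), `affine` (4x4; sform if set, else pixdim
#'   scaling), `pixdim`, `datatype` (NIfTI code).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L)
    stop("truncated NIfTI header in ", path, call. = FALSE)
  parse <- function(endian) {
    ri <- function(off, size, n = 1) readBin(hdr_raw[(off + 1):(off + size * n)],
      "integer", n = n, size = size, endian = endian)
    rf <- function(off, n = 1) readBin(hdr_raw[(off + 1):(off + 4 * n)],
      "double", n = n, size = 4L, endian = endian)
    list(sizeof_hdr = ri(0, 4), dim = ri(40, 2, 8), datatype = ri(70, 2),
         pixdim = rf(76, 8), vox_offset = rf(108), scl_slope = rf(112),
         scl_inter = rf(116), sform_code = ri(254, 2), srow = rf(280, 12),
         magic = rawToChar(hdr_raw[345:347]), endian = endian)
  }
  h <- parse("little")
  if (h$sizeof_hdr != 348L) h <- parse("big")
  if (h$sizeof_hdr != 348L)
    stop(path, " is not a NIfTI-1 file", call. = FALSE)
  if (!h$magic %in% c("n+1", "ni1"))
    stop(path, ": unsupported NIfTI magic '", h$magic, "'", call. = FALSE)
  nd <- h$dim[1]
  if (nd < 1 || nd > 4)
    stop(path, ": only 3D/4D volumes supported (dim0 = ", nd, ")",
         call. = FALSE)
  shape <- h$dim[1 + seq_len(nd)]
  dt <- nifti_datatypes[[as.character(h$datatype)]]
  if (is.null(dt))
    stop(path, ": unsupported NIfTI datatype code ", h$datatype,
         call. = FALSE)
  # skip from end of header to vox_offset
  skip <- round(h$vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = h$endian)
  if (length(vals) < n)
    stop(path, ": truncated data section", call. = FALSE)
  if (is.finite(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0))
    vals <- vals * h$scl_slope + h$scl_inter
  affine <- diag(4)
  if (h$sform_code > 0) {
    affine[1:3, ] <- matrix(h$srow, 3, 4, byrow = TRUE)
  } else {
    diag(affine)[1:3] <- h$pixdim[2:4]
  }
  list(data = array(vals, shape), affine = affine,
       pixdim = h$pixdim[1 + seq_len(nd)], datatype = h$datatype)
}
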