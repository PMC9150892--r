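#' 3D scalar volume
#'
#' Minimal carrier for phantom images, masks and parameter maps: a 3D
#' array, voxel sizes (mm) and a 4x4 voxel-to-world affine in RAS
#' orientation. Voxel indices are 0-based in world computations, with voxel
#' centres at `(i + 0.5) * voxel_mm` under the default affine.
#'
#' @param data 3D numeric (or logical) array.
#' @param voxel_mm Voxel edge lengths (mm); scalar or length-3 vector.
#' @param affine Optional 4x4 voxel-index-to-world-mm transform; default is
#'   a diagonal scaling by `voxel_mm` with a half-voxel origin shift so the
#'   centre of voxel (0,0,0) sits at `voxel_mm / 2`.
#' @param meta Free-form named list of header metadata.
#' @return An object of class `volume`.
#' @export
volume <- function(data, voxel_mm, affine = NULL, meta = list()) {
  stop_if_not(is.array(data), length(dim(data)) == 3,
              msg = "data must be a 3D array")
  if (is.logical(data)) storage.mode(data) <- "double"
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3)
  stop_if_not(all(voxel_mm > 0), msg = "voxel sizes must be positive")
  if (is.null(affine)) {
    affine <- diag(c(voxel_mm, 1))
    affine[1:3, 4] <- voxel_mm / 2
  }
  stop_if_not(is.matrix(affine), all(dim(affine) == c(4, 4)),
              abs(det(affine)) > 0,
              msg = "affine must be an invertible 4x4 matrix")
  structure(list(data = data, voxel_mm = voxel_mm, affine = affine,
                 meta = meta),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat("volume:", paste(dim(x$data), collapse = " x "), "voxels,",
      paste(signif(x$voxel_mm, 4), collapse = " x "), "mm; range [",
      signif(min(x$data), 5), ",", signif(max(x$data), 5), "]\n")
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Check that two volumes share a grid
#' @param a,b `volume` objects.
#' @param what Label used in the error message.
#' @return Invisibly TRUE; errors on mismatch.
#' @keywords internal
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$voxel_mm - b$voxel_mm)) > 1e-9)
    stop(what, " are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

#' Require isotropic voxels
#' @param vol `volume`.
#' @return The common voxel size (mm); errors if anisotropic.
#' @keywords internal
require_isotropic <- function(vol) {
  if (diff(range(vol$voxel_mm)) > 1e-9 * mean(vol$voxel_mm))
    stop("this operation requires isotropic voxels; got ",
         paste(signif(vol$voxel_mm, 4), collapse = " x "), call. = FALSE)
  vol$voxel_mm[1]
}

# ---------------------------------------------------------------------------
# Minimal NIfTI-1 I/O. No NIfTI package ships with the target R library, so
# the single-file .nii layout (348-byte header + float64 data, optional
# gzip) is read and written directly. Little-endian only on write; both
# endiannesses on read.
# ---------------------------------------------------------------------------

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE), # uint8
  `4`  = list(what = "integer", size = 2, signed = TRUE),  # int16
  `8`  = list(what = "integer", size = 4, signed = TRUE),  # int32
  `16` = list(what = "double",  size = 4, signed = TRUE),  # float32
  `64` = list(what = "double",  size = 8, signed = TRUE)   # float64
)

open_nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads single-file `.nii` / `.nii.gz` images (datatypes uint8, int16,
#' int32, float32, float64), applying scl_slope/scl_inter when set. The
#' sform (or, failing that, qform translation-free fallback of pixdim
#' scaling) provides the affine.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("NIfTI file not found: ", path, call. = FALSE)
  con <- open_nifti_con(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348)
  if (length(hdr_raw) < 348)
    stop("malformed NIfTI header (file too short): ", path, call. = FALSE)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
    if (sizeof_hdr != 348L)
      stop("malformed NIfTI header (sizeof_hdr != 348): ", path,
           call. = FALSE)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("malformed NIfTI header (bad magic): ", path, call. = FALSE)
  rd <- function(idx, what, size, n = 1)
    readBin(hdr_raw[idx], what, n = n, size = size, endian = endian)
  dims <- rd(41:56, "integer", 2, n = 8)
  ndim <- dims[1]
  if (ndim < 3) dims[(ndim + 2):4] <- 1L
  shape <- dims[2:4]
  datatype <- rd(71:72, "integer", 2)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype ", datatype, " in ", path,
         call. = FALSE)
  pixdim <- rd(77:108, "double", 4, n = 8)
  vox_offset <- rd(109:112, "double", 4)
  scl_slope <- rd(113:116, "double", 4)
  scl_inter <- rd(117:120, "double", 4)
  sform_code <- rd(255:256, "integer", 2)
  srow <- matrix(rd(281:328, "double", 4, n = 12), nrow = 3, byrow = TRUE)
  n_vox <- prod(shape)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < n_vox)
    stop("truncated NIfTI data section: ", path, call. = FALSE)
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  voxel_mm <- pixdim[2:4]
  affine <- diag(4)
  if (sform_code > 0) {
    affine[1:3, ] <- srow
  } else {
    affine <- diag(c(voxel_mm, 1))
    affine[1:3, 4] <- voxel_mm / 2
  }
  volume(array(vals, dim = shape), voxel_mm = voxel_mm, affine = affine,
         meta = list(datatype = datatype, path = path))
}

#' Write a NIfTI-1 volume
#'
#' Writes a single-file little-endian `.nii` (gzipped when the path ends in
#' `.gz`) with float64 data, so that write-then-read round-trips are exact.
#'
#' @param vol A [volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stop_if_not(inherits(vol, "volume"), msg = "vol must be a volume")
  con <- open_nifti_con(path, "wb")
  on.exit(close(con))
  shape <- dim(vol$data)
  wr_i32 <- function(x) writeBin(as.integer(x), con, size = 4,
                                 endian = "little")
  wr_i16 <- function(x) writeBin(as.integer(x), con, size = 2,
                                 endian = "little")
  wr_f32 <- function(x) writeBin(as.double(x), con, size = 4,
                                 endian = "little")
  wr_raw0 <- function(n) writeBin(raw(n), con)
  wr_i32(348)                      # sizeof_hdr
  wr_raw0(36)                      # data_type, db_name, extents, ...
  wr_i16(c(3, shape, 1, 1, 1, 1))  # dim
  wr_f32(c(0, 0, 0))               # intent_p1..p3
  wr_i16(0)                        # intent_code
  wr_i16(64)                       # datatype: float64
  wr_i16(64)                       # bitpix
  wr_i16(0)                        # slice_start
  wr_f32(c(1, vol$voxel_mm, 1, 1, 1, 1)) # pixdim
  wr_f32(352)                      # vox_offset
  wr_f32(1)                        # scl_slope
  wr_f32(0)                        # scl_inter
  wr_raw0(4)                       # slice_end, slice_code, xyzt_units
  wr_f32(c(0, 0))                  # cal_max, cal_min
  wr_f32(c(0, 0))                  # slice_duration, toffset
  wr_i32(c(0, 0))                  # glmax, glmin
  wr_raw0(80 + 24)                 # descrip, aux_file
  wr_i16(0)                        # qform_code
  wr_i16(1)                        # sform_code
  wr_f32(rep(0, 6))                # quatern b,c,d, qoffset x,y,z
  wr_f32(t(vol$affine[1:3, , drop = FALSE])) # srow_x/y/z
  wr_raw0(16)                      # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wr_raw0(4)                       # extension flag
  writeBin(as.double(vol$data), con, size = 8, endian = "little")
  invisible(path)
}
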