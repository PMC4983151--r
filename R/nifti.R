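#' Binary volume mask on a voxel grid
#'
#' Holds the in-mask voxel indices of a NIfTI-style volume together with the
#' 4x4 affine mapping 0-based voxel indices to RAS millimetres. The affine
#' maps the voxel CENTRE, following the NIfTI convention.
#'
#' @param dim integer triple, grid shape in voxels.
#' @param affine 4x4 numeric voxel-index-to-mm matrix; must be invertible.
#' @param ijk integer matrix of 0-based in-mask voxel indices (one row per
#'   voxel, columns i/j/k).
#' @return An object of class `volume_mask`.
#' @export
volume_mask <- function(dim, affine, ijk) {
  dim <- as.integer(dim)
  affine <- as.matrix(affine)
  ijk <- as.matrix(ijk)
  storage.mode(ijk) <- "integer"
  if (length(dim) != 3L || any(dim < 1L)) stop("dim must be 3 positive integers")
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    stop("affine is not invertible")
  if (nrow(ijk) > 0L) {
    if (ncol(ijk) != 3L) stop("ijk must have 3 columns")
    bad <- ijk[, 1L] < 0L | ijk[, 1L] >= dim[1L] |
           ijk[, 2L] < 0L | ijk[, 2L] >= dim[2L] |
           ijk[, 3L] < 0L | ijk[, 3L] >= dim[3L]
    if (any(bad)) stop("in-mask voxel indices outside the grid")
  }
  structure(list(dim = dim, affine = affine, ijk = ijk), class = "volume_mask")
}

#' @export
print.volume_mask <- function(x, ...) {
  cat(sprintf("<volume_mask: %dx%dx%d grid, %d in-mask voxels>\n",
              x$dim[1L], x$dim[2L], x$dim[3L], nrow(x$ijk)))
  invisible(x)
}

#' Millimetre centres of the in-mask voxels
#' @param mask a [volume_mask()].
#' @return numeric matrix, one mm coordinate row per in-mask voxel.
#' @export
mask_voxel_centres <- function(mask) {
  n <- nrow(mask$ijk)
  hom <- cbind(mask$ijk, rep(1, n))
  out <- hom %*% t(mask$affine)
  out[, 1:3, drop = FALSE]
}

# linear key for voxel set membership (0-based indices)
voxel_key <- function(ijk, dim) {
  as.numeric(ijk[, 1L]) + as.numeric(dim[1L]) *
    (as.numeric(ijk[, 2L]) + as.numeric(dim[2L]) * as.numeric(ijk[, 3L]))
}

# --- NIfTI-1 ---------------------------------------------------------------

nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE))

read_nifti_header_and_data <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (sizeof_hdr != 348L)
    stop(sprintf("%s is not a little-endian NIfTI-1 file (sizeof_hdr = %d)", path, sizeof_hdr))
  readBin(con, "raw", 36L)                                    # unused fields
  dim <- readBin(con, "integer", 8L, size = 2L, endian = "little")
  readBin(con, "double", 3L, size = 4L, endian = "little")     # intent_p1..p3
  readBin(con, "integer", 1L, size = 2L, endian = "little")    # intent_code
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "integer", 1L, size = 2L, endian = "little")    # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = "little")    # slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = "little")
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = "little")
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = "little")
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = "little")
  readBin(con, "raw", 4L)                                      # slice_end, slice_code, xyzt_units
  readBin(con, "double", 3L, size = 4L, endian = "little")     # cal_max, cal_min, slice_duration
  readBin(con, "double", 1L, size = 4L, endian = "little")     # toffset
  readBin(con, "integer", 2L, size = 4L, endian = "little")    # glmax, glmin
  readBin(con, "raw", 80L + 24L)                               # descrip, aux_file
  qform_code <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  quat <- readBin(con, "double", 6L, size = 4L, endian = "little")  # b,c,d, qoffset x,y,z
  srow <- matrix(readBin(con, "double", 12L, size = 4L, endian = "little"),
                 nrow = 3L, byrow = TRUE)
  readBin(con, "raw", 16L + 4L)                                # intent_name, magic
  consumed <- 348L
  if (vox_offset > consumed) readBin(con, "raw", as.integer(vox_offset) - consumed)
  nd <- dim[1L]
  shape <- dim[2:(1L + max(nd, 3L))]
  shape[shape == 0L] <- 1L
  nvox <- prod(as.numeric(shape))
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop(sprintf("unsupported NIfTI datatype code %d in %s", datatype, path))
  data <- readBin(con, dt$what, n = nvox, size = dt$size, endian = "little",
                  signed = dt$signed)
  if (length(data) < nvox)
    stop(sprintf("truncated NIfTI data in %s: %d of %g voxels read", path, length(data), nvox))
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  affine <- nifti_affine(sform_code, srow, qform_code, quat, pixdim)
  list(dim = as.integer(shape[1:3]), affine = affine,
       data = array(data, dim = shape[1:3]))
}

nifti_affine <- function(sform_code, srow, qform_code, quat, pixdim) {
  if (sform_code > 0L) {
    return(rbind(srow, c(0, 0, 0, 1)))
  }
  if (qform_code > 0L) {
    b <- quat[1L]; c_ <- quat[2L]; d <- quat[3L]
    a2 <- 1 - b * b - c_ * c_ - d * d
    a <- sqrt(max(a2, 0))
    qfac <- if (pixdim[1L] < 0) -1 else 1
    R <- matrix(c(
      a * a + b * b - c_ * c_ - d * d, 2 * (b * c_ - a * d), 2 * (b * d + a * c_),
      2 * (b * c_ + a * d), a * a + c_ * c_ - b * b - d * d, 2 * (c_ * d - a * b),
      2 * (b * d - a * c_), 2 * (c_ * d + a * b), a * a + d * d - b * b - c_ * c_),
      nrow = 3L, byrow = TRUE)
    S <- diag(c(pixdim[2L], pixdim[3L], qfac * pixdim[4L]))
    aff <- diag(4)
    aff[1:3, 1:3] <- R %*% S
    aff[1:3, 4L] <- quat[4:6]
    return(aff)
  }
  # fallback: voxel-size scaling only
  aff <- diag(4)
  diag(aff)[1:3] <- ifelse(pixdim[2:4] > 0, pixdim[2:4], 1)
  aff
}

#' Read a NIfTI volume as a binary mask
#'
#' Voxels with value > 0 are in-mask. The affine is taken from the sform when
#' its code is positive, else the qform, else plain voxel-size scaling.
#'
#' @param path path to a `.nii` or `.nii.gz` file (little-endian NIfTI-1).
#' @return A [volume_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("mask file not found: %s", path))
  h <- read_nifti_header_and_data(path)
  pos <- which(h$data > 0)
  if (length(pos) > 0L) {
    pos0 <- pos - 1L
    i <- pos0 %% h$dim[1L]
    j <- (pos0 %/% h$dim[1L]) %% h$dim[2L]
    k <- pos0 %/% (h$dim[1L] * h$dim[2L])
    ijk <- cbind(i, j, k)
  } else {
    ijk <- matrix(integer(), 0L, 3L)
  }
  volume_mask(h$dim, h$affine, ijk)
}

#' Write a labelled volume as NIfTI-1
#'
#' Stores `values` (default 1 for every in-mask voxel) on the mask's grid as
#' int16 with the mask's affine in the sform (code 1); used both for mask
#' round-trips and for exporting CC segment labels.
#'
#' @param mask a [volume_mask()].
#' @param path destination `.nii` or `.nii.gz` path.
#' @param values optional integer vector, one label per in-mask voxel.
#' @export
write_mask <- function(mask, path, values = NULL) {
  stopifnot(inherits(mask, "volume_mask"))
  if (is.null(values)) values <- rep(1L, nrow(mask$ijk))
  if (length(values) != nrow(mask$ijk))
    stop("values must have one entry per in-mask voxel")
  vol <- array(0L, dim = mask$dim)
  if (nrow(mask$ijk) > 0L)
    vol[mask$ijk + 1L] <- as.integer(values)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(rep(as.raw(0L), n), con)
  pixdim <- sqrt(colSums(mask$affine[1:3, 1:3]^2))
  w_i32(348L); w_raw(36L)
  w_i16(c(3L, mask$dim, 1L, 1L, 1L, 1L))         # dim[0..7]
  w_f32(c(0, 0, 0)); w_i16(0L)                   # intent
  w_i16(4L); w_i16(16L); w_i16(0L)               # datatype int16, bitpix, slice_start
  w_f32(c(1, pixdim, 1, 1, 1, 1))                # pixdim[0..7]
  w_f32(352L); w_f32(1L); w_f32(0L)              # vox_offset, scl_slope, scl_inter
  w_raw(4L); w_f32(c(0, 0, 0)); w_f32(0L); w_i32(c(0L, 0L))
  w_raw(80L + 24L)
  w_i16(0L); w_i16(1L)                           # qform 0, sform 1
  w_f32(rep(0, 6))                               # quaternion + qoffset
  w_f32(as.vector(t(mask$affine[1:3, ])))        # srow_x, srow_y, srow_z
  w_raw(16L)
  writeChar("n+1", con, nchars = 3L, eos = NULL); w_raw(1L)
  w_raw(4L)                                      # extension flag
  writeBin(as.vector(vol), con, size = 2L, endian = "little")
  invisible(path)
}
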