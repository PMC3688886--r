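# Minimal NIfTI-1 reader/writer. The environment offers no R NIfTI package,
# so the subset of the format this package needs (single-component 3-D
# volumes, little-endian, datatypes uint8/int16/int32/float32/float64,
# optional gzip container) is implemented directly against the NIfTI-1
# header layout. Affines: sform preferred, then qform, then pixdim diagonal.

NIFTI_DTYPES <- list(
  "2"  = list(what = "integer", size = 1, signed = FALSE),  # uint8
  "4"  = list(what = "integer", size = 2, signed = TRUE),   # int16
  "8"  = list(what = "integer", size = 4, signed = TRUE),   # int32
  "16" = list(what = "numeric", size = 4, signed = TRUE),   # float32
  "64" = list(what = "numeric", size = 8, signed = TRUE)    # float64
)

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(sizeof_hdr, 348L)) {
    stop("not a little-endian NIfTI-1 file (sizeof_hdr = ", sizeof_hdr, "): ", path)
  }
  readBin(con, "raw", 36)                                   # unused fields
  dim <- readBin(con, "integer", 8, size = 2, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")   # intent_p1..p3
  readBin(con, "integer", 1, size = 2, endian = "little")   # intent_code
  datatype <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "integer", 1, size = 2, endian = "little")   # bitpix
  readBin(con, "integer", 1, size = 2, endian = "little")   # slice_start
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = "little")
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = "little")
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = "little")
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = "little")
  # slice_end(2) slice_code(1) xyzt_units(1) cal_max(4) cal_min(4)
  # slice_duration(4) toffset(4) glmax(4) glmin(4) descrip(80) aux_file(24)
  readBin(con, "raw", 132)
  qform_code <- readBin(con, "integer", 1, size = 2, endian = "little")
  sform_code <- readBin(con, "integer", 1, size = 2, endian = "little")
  quatern <- readBin(con, "numeric", 6, size = 4, endian = "little")
  srow <- readBin(con, "numeric", 12, size = 4, endian = "little")
  readBin(con, "raw", 16 + 4)                               # intent_name + magic
  ndim <- dim[1]
  if (ndim != 3) {
    stop("expected a 3-D single-component NIfTI, got ndim = ", ndim, ": ", path)
  }
  dims <- dim[2:4]
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype, ": ", path)
  skip <- max(0, round(vox_offset) - 348)
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = "little")
  if (length(vals) != n) stop("truncated NIfTI data: ", path)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  spacing <- abs(pixdim[2:4])
  spacing[spacing == 0] <- 1
  affine <- nifti_affine(sform_code, srow, qform_code, quatern, pixdim, spacing)
  list(values = array(vals, dim = dims), dims = dims, spacing = spacing,
       affine = affine, datatype = datatype)
}

nifti_affine <- function(sform_code, srow, qform_code, quatern, pixdim, spacing) {
  if (sform_code > 0) {
    aff <- diag(4)
    aff[1, ] <- srow[1:4]; aff[2, ] <- srow[5:8]; aff[3, ] <- srow[9:12]
    return(aff)
  }
  if (qform_code > 0) {
    b <- quatern[1]; c <- quatern[2]; d <- quatern[3]
    a2 <- 1 - b * b - c * c - d * d
    a <- if (a2 > 0) sqrt(a2) else 0
    R <- matrix(c(
      a * a + b * b - c * c - d * d, 2 * (b * c - a * d), 2 * (b * d + a * c),
      2 * (b * c + a * d), a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
      2 * (b * d - a * c), 2 * (c * d + a * b), a * a + d * d - b * b - c * c
    ), 3, 3, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    R[, 3] <- R[, 3] * qfac
    aff <- diag(4)
    aff[1:3, 1:3] <- R %*% diag(spacing)
    aff[1:3, 4] <- quatern[4:6]
    return(aff)
  }
  diag(c(spacing, 1))
}

#' Read a 3-D intensity volume from NIfTI-1
#'
#' Reads a single-component 3-D `.nii`/`.nii.gz` file; values are cast to
#' double and the grid (dims, spacing, affine) is populated from the header.
#' 2-D or 4-D files, unsupported datatypes and singular affines are errors.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [intensity_volume].
#' @export
read_volume <- function(path) {
  raw <- read_nifti_raw(path)
  if (!all(is.finite(raw$values))) stop("non-finite voxel values in ", path)
  grid <- voxel_grid(raw$dims, raw$spacing, raw$affine)
  intensity_volume(raw$values, grid)
}

#' Read a label volume from NIfTI-1 with dictionary verification
#'
#' Values must be integers to within 1e-6; every nonzero label must appear in
#' `dictionary` (0 is reserved for unlabeled/background).
#'
#' @inheritParams read_volume
#' @param dictionary named character vector mapping label id to structure name.
#' @return A [label_volume].
#' @export
read_labels <- function(path, dictionary) {
  raw <- read_nifti_raw(path)
  r <- round(raw$values)
  if (max(abs(raw$values - r)) > 1e-6) {
    stop("non-integer label values in ", path)
  }
  grid <- voxel_grid(raw$dims, raw$spacing, raw$affine)
  label_volume(r, grid, dictionary)
}

#' Write a volume to NIfTI-1
#'
#' Intensity volumes are written as float32, label volumes as int16. The grid
#' affine is stored in the sform (code 2); spacing goes to pixdim.
#'
#' @param volume an [intensity_volume] or [label_volume].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  is_lab <- inherits(volume, "label_volume")
  data <- if (is_lab) volume$labels else volume$values
  g <- volume$grid
  if (is_lab && max(data) > 32767) stop("label ids exceed int16 range")
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348, 4)                                  # sizeof_hdr
  writeBin(raw(36), con)                      # data_type..dim_info
  wi(c(3, g$dims, 1, 1, 1, 1), 2)             # dim
  wf(c(0, 0, 0))                              # intent_p1..p3
  wi(0, 2)                                    # intent_code
  wi(if (is_lab) 4 else 16, 2)                # datatype
  wi(if (is_lab) 16 else 32, 2)               # bitpix
  wi(0, 2)                                    # slice_start
  wf(c(1, g$spacing, 1, 1, 1, 1))             # pixdim (qfac = 1)
  wf(352)                                     # vox_offset
  wf(c(0, 0))                                 # scl_slope, scl_inter
  wi(0, 2); writeBin(raw(2), con)             # slice_end, slice_code+xyzt_units
  wf(c(0, 0, 0))                              # cal_max, cal_min, slice_duration
  wf(0); wi(c(0, 0), 4)                       # toffset, glmax, glmin
  writeBin(raw(80 + 24), con)                 # descrip, aux_file
  wi(c(0, 2), 2)                              # qform_code = 0, sform_code = 2
  wf(rep(0, 6))                               # quatern b,c,d + offsets
  wf(t(g$affine[1:3, ]))                      # srow_x, srow_y, srow_z
  writeBin(raw(16), con)                      # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  writeBin(raw(4), con)                       # pad to vox_offset 352
  if (is_lab) {
    writeBin(as.integer(data), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read/write a label dictionary as JSON
#'
#' The dictionary file is a JSON object mapping label id to structure name.
#'
#' @param path JSON file path.
#' @return `read_dictionary`: named character vector.
#' @export
read_dictionary <- function(path) {
  x <- jsonlite::read_json(path)
  validate_dictionary(stats::setNames(as.character(unlist(x)), names(x)))
}

#' @rdname read_dictionary
#' @param dictionary named character vector mapping label id to name.
#' @export
write_dictionary <- function(dictionary, path) {
  dictionary <- validate_dictionary(dictionary)
  jsonlite::write_json(as.list(dictionary), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
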