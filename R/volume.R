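#' Voxel grids and typed volumes
#'
#' A `voxel_grid` describes the lattice a volume lives on: integer dimensions,
#' voxel spacing in mm, and a 4x4 voxel-to-world affine (mm). Voxel indices are
#' 0-based throughout the package and boxes are half-open `[lower, upper)`.
#'
#' @param dims integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, voxel size in mm (all > 0).
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(spacing)` with a
#'   zero origin.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims, spacing = c(1, 1, 1), affine = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1))
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- matrix(as.numeric(affine), 4, 4)
  if (abs(det(affine[1:3, 1:3])) <= 0) {
    stop("voxel_grid: affine 3x3 block is singular")
  }
  structure(list(dims = dims, spacing = spacing, affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid:", paste(x$dims, collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 5), collapse = " x "), "mm\n")
  invisible(x)
}

grid_equal <- function(a, b, tol = 1e-5) {
  identical(a$dims, b$dims) &&
    max(abs(a$affine - b$affine)) < tol
}

#' Intensity volume
#'
#' A real-valued scalar volume on a [voxel_grid]. Values must be finite.
#'
#' @param values 3-D numeric array matching `grid$dims`.
#' @param grid a [voxel_grid].
#' @return An object of class `intensity_volume` with fields `values`, `grid`.
#' @export
intensity_volume <- function(values, grid) {
  values <- array(as.numeric(values), dim = grid$dims)
  if (!all(is.finite(values))) stop("intensity_volume: non-finite values")
  structure(list(values = values, grid = grid), class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat("intensity_volume on ")
  print(x$grid)
  cat("  range:", paste(signif(range(x$values), 6), collapse = " .. "), "\n")
  invisible(x)
}

#' Label volume
#'
#' Non-negative integer labels on a [voxel_grid] with a dictionary mapping
#' label id to structure name. Label 0 is reserved for unlabeled/background
#' and need not appear in the dictionary.
#'
#' @param labels 3-D integer array matching `grid$dims`.
#' @param grid a [voxel_grid].
#' @param dictionary named character vector: names are label ids, values are
#'   structure names (e.g. `c("1" = "hippocampus")`).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, grid, dictionary = character()) {
  labels <- array(as.integer(round(labels)), dim = grid$dims)
  if (anyNA(labels) || any(labels < 0)) {
    stop("label_volume: labels must be non-negative integers")
  }
  dictionary <- validate_dictionary(dictionary)
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(present, as.integer(names(dictionary)))
  if (length(missing)) {
    stop("label_volume: labels absent from dictionary: ",
         paste(missing, collapse = ", "))
  }
  structure(list(labels = labels, grid = grid, dictionary = dictionary),
            class = "label_volume")
}

validate_dictionary <- function(dictionary) {
  if (is.list(dictionary)) dictionary <- unlist(dictionary)
  dictionary <- stats::setNames(as.character(dictionary), names(dictionary))
  if (length(dictionary)) {
    ids <- suppressWarnings(as.integer(names(dictionary)))
    if (anyNA(ids) || any(ids <= 0)) {
      stop("dictionary names must be positive integer label ids")
    }
    if (anyDuplicated(ids)) stop("duplicated label ids in dictionary")
    dictionary <- dictionary[order(ids)]
  }
  dictionary
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume on ")
  print(x$grid)
  tab <- table(x$labels[x$labels > 0])
  for (id in names(tab)) {
    cat(sprintf("  %s (%s): %d voxels\n", id,
                if (id %in% names(x$dictionary)) x$dictionary[[id]] else "?",
                as.integer(tab[[id]])))
  }
  invisible(x)
}

#' Cuboid region of interest
#'
#' Half-open axis-aligned voxel box `[lower, upper)` in 0-based indices.
#'
#' @param lower,upper integer vectors of length 3 with `lower < upper`.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(lower, upper) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  stopifnot(length(lower) == 3, length(upper) == 3)
  if (any(lower < 0) || any(upper <= lower)) {
    stop("roi_box: need 0 <= lower < upper per axis")
  }
  structure(list(lower = lower, upper = upper), class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("roi_box [%s) x [%s) x [%s), %d voxels\n",
              paste(c(x$lower[1], x$upper[1]), collapse = ", "),
              paste(c(x$lower[2], x$upper[2]), collapse = ", "),
              paste(c(x$lower[3], x$upper[3]), collapse = ", "),
              prod(x$upper - x$lower)))
  invisible(x)
}

box_dims <- function(box) box$upper - box$lower

check_box_in_grid <- function(box, grid) {
  if (any(box$upper > grid$dims)) stop("roi_box exceeds grid dimensions")
  invisible(TRUE)
}

#' Cuboid ROI around all labeled structures
#'
#' Computes the smallest axis-aligned box containing every nonzero label in
#' every input label volume, dilates it by `margin_vox` voxels and clips it to
#' the grid. This is the cuboid region of interest inside which fusion and
#' generic-tissue labeling operate.
#'
#' @param label_volumes a [label_volume] or list of them, all on one grid.
#' @param margin_vox non-negative integer dilation in voxels (default 4, which
#'   gives overlapping chart "open sets" room at structure boundaries).
#' @return A [roi_box].
#' @export
compute_roi <- function(label_volumes, margin_vox = 4L) {
  if (inherits(label_volumes, "label_volume")) label_volumes <- list(label_volumes)
  stopifnot(length(label_volumes) >= 1, margin_vox >= 0)
  g <- label_volumes[[1]]$grid
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (lv in label_volumes) {
    if (!grid_equal(lv$grid, g)) stop("compute_roi: volumes on different grids")
    idx <- which(lv$labels != 0L, arr.ind = TRUE)
    if (nrow(idx)) {
      lo <- pmin(lo, apply(idx, 2, min) - 1)  # to 0-based
      hi <- pmax(hi, apply(idx, 2, max) - 1)
    }
  }
  if (!all(is.finite(lo))) stop("compute_roi: no nonzero labels in any input")
  lower <- pmax(0L, as.integer(lo) - as.integer(margin_vox))
  upper <- pmin(g$dims, as.integer(hi) + 1L + as.integer(margin_vox))
  roi_box(lower, upper)
}

#' Crop a volume to a box / restore it to the full grid
#'
#' `crop` returns the sub-volume on the box with an affine translated so that
#' world coordinates are preserved (voxel (0,0,0) of the cropped volume sits at
#' the world position of `box$lower`). `uncrop` places a cropped volume back
#' into a full grid, filling outside the box with `fill`.
#'
#' @param volume an [intensity_volume] or [label_volume].
#' @param box a [roi_box] inside the volume's grid.
#' @return A volume of the same class.
#' @export
crop <- function(volume, box) {
  g <- volume$grid
  check_box_in_grid(box, g)
  i <- (box$lower[1] + 1):box$upper[1]
  j <- (box$lower[2] + 1):box$upper[2]
  k <- (box$lower[3] + 1):box$upper[3]
  aff <- g$affine
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% box$lower
  sub_grid <- voxel_grid(box_dims(box), g$spacing, aff)
  if (inherits(volume, "label_volume")) {
    label_volume(volume$labels[i, j, k, drop = FALSE], sub_grid, volume$dictionary)
  } else {
    intensity_volume(volume$values[i, j, k, drop = FALSE], sub_grid)
  }
}

#' @rdname crop
#' @param full_grid the [voxel_grid] to restore onto.
#' @param fill value used outside the box (default 0).
#' @export
uncrop <- function(volume, box, full_grid, fill = 0) {
  check_box_in_grid(box, full_grid)
  stopifnot(identical(box_dims(box), volume$grid$dims))
  i <- (box$lower[1] + 1):box$upper[1]
  j <- (box$lower[2] + 1):box$upper[2]
  k <- (box$lower[3] + 1):box$upper[3]
  if (inherits(volume, "label_volume")) {
    full <- array(as.integer(fill), dim = full_grid$dims)
    full[i, j, k] <- volume$labels
    label_volume(full, full_grid, volume$dictionary)
  } else {
    full <- array(as.numeric(fill), dim = full_grid$dims)
    full[i, j, k] <- volume$values
    intensity_volume(full, full_grid)
  }
}

#' Resample a volume onto a target grid
#'
#' Maps each target voxel through both affines into the source voxel lattice
#' and interpolates (`"linear"` for intensities, `"nearest"` for labels).
#' Atlases are assumed pre-resampled onto the target grid before fusion; this
#' is the supporting utility for that step.
#'
#' @param volume an [intensity_volume] or [label_volume].
#' @param grid the target [voxel_grid].
#' @param method `"linear"` or `"nearest"` (label volumes force `"nearest"`).
#' @return A volume of the same class on `grid`.
#' @export
resample_to <- function(volume, grid, method = c("linear", "nearest")) {
  method <- match.arg(method)
  src <- volume$grid
  co <- grid_coords(grid$dims)            # 0-based target voxel coords, 3 x n
  world <- grid$affine %*% rbind(co, 1)
  svox <- solve(src$affine) %*% world     # 0-based source voxel coords
  if (inherits(volume, "label_volume")) {
    lab <- cpp_interp3_nn(volume$labels, svox[1, ], svox[2, ], svox[3, ])
    label_volume(array(lab, grid$dims), grid, volume$dictionary)
  } else if (method == "nearest") {
    v <- cpp_interp3_nn(array(as.integer(round(volume$values)), src$dims),
                        svox[1, ], svox[2, ], svox[3, ])
    intensity_volume(array(as.numeric(v), grid$dims), grid)
  } else {
    v <- cpp_interp3(volume$values, svox[1, ], svox[2, ], svox[3, ])
    intensity_volume(array(v, grid$dims), grid)
  }
}

# 0-based voxel coordinates of every lattice point, as a 3 x prod(dims) matrix.
grid_coords <- function(dims) {
  rbind(
    rep.int(seq_len(dims[1]) - 1, times = dims[2] * dims[3]),
    rep.int(rep(seq_len(dims[2]) - 1, each = dims[1]), times = dims[3]),
    rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2])
  )
}
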