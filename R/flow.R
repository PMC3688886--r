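# Diffeomorphisms as sampled coordinate maps, built by integrating velocity
# fields, plus image/label warping. Maps are (n1,n2,n3,3) arrays of 0-based
# voxel coordinates: forward phi sends atlas points to target positions, and
# warping pulls values back through the inverse.

identity_map <- function(dims) {
  m <- array(0, c(dims, 3))
  m[, , , 1] <- rep.int(seq_len(dims[1]) - 1, times = dims[2] * dims[3])
  m[, , , 2] <- rep.int(rep(seq_len(dims[2]) - 1, each = dims[1]), dims[3])
  m[, , , 3] <- rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2])
  m
}

# Evaluate a 3-component field at arbitrary 0-based coordinates (edge clamp).
interp_field <- function(field, cx, cy, cz) {
  d <- dim(field)[1:3]
  out <- array(0, c(length(cx), 3))
  for (c in 1:3) {
    out[, c] <- cpp_interp3(array(field[, , , c], d), cx, cy, cz)
  }
  out
}

# Composition (A o B)(x) = A(B(x)) for coordinate maps on one grid.
compose_maps <- function(A, B) {
  d <- dim(A)
  out <- A
  vals <- interp_field(A, as.vector(B[, , , 1]), as.vector(B[, , , 2]),
                       as.vector(B[, , , 3]))
  for (c in 1:3) out[, , , c] <- array(vals[, c], d[1:3])
  out
}

#' Diffeomorphism on a voxel grid
#'
#' Holds forward and inverse coordinate maps sampled on the lattice. The
#' constructor checks inverse consistency (`max |phi(phi^-1(x)) - x|` below
#' `tol`, default 0.5 voxel, measured away from the grid edge where clamping
#' interferes) and positivity of the forward Jacobian determinant at interior
#' voxels.
#'
#' @param forward,inverse `(n1,n2,n3,3)` arrays of 0-based voxel coordinates.
#' @param check validate invariants (default TRUE).
#' @param tol inverse-consistency tolerance in voxels.
#' @return An object of class `diffeomorphism`.
#' @export
diffeomorphism <- function(forward, inverse, check = TRUE, tol = 0.5) {
  d <- dim(forward)
  stopifnot(length(d) == 4, d[4] == 3, identical(dim(inverse), d))
  phi <- structure(list(forward = forward, inverse = inverse, dims = d[1:3]),
                   class = "diffeomorphism")
  if (check) {
    jmin <- min_interior_jacobian(forward)
    if (is.finite(jmin) && jmin <= 0) {
      stop("diffeomorphism: non-positive Jacobian determinant (min ",
           signif(jmin, 4), ")")
    }
    err <- inverse_consistency_error(phi)
    if (is.finite(err) && err > tol) {
      stop("diffeomorphism: inverse consistency error ", signif(err, 4),
           " vox exceeds tolerance ", tol)
    }
  }
  phi
}

#' @export
print.diffeomorphism <- function(x, ...) {
  disp <- max(abs(x$forward - identity_map(x$dims)))
  cat(sprintf("diffeomorphism on %s grid, max displacement %.3f vox\n",
              paste(x$dims, collapse = "x"), disp))
  invisible(x)
}

min_interior_jacobian <- function(map) {
  d <- dim(map)[1:3]
  if (any(d < 3)) return(Inf)
  jd <- cpp_jacdet3(map)
  min(jd[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)])
}

# Max |phi(phi^-1(x)) - x| over voxels whose round trip stays clear of the
# clamped boundary band.
inverse_consistency_error <- function(phi, band = 2) {
  d <- phi$dims
  comp <- compose_maps(phi$forward, phi$inverse)
  idm <- identity_map(d)
  err <- sqrt(rowSums(matrix((comp - idm), ncol = 3)^2))
  inner <- rep(TRUE, prod(d))
  for (c in 1:3) {
    co <- as.vector(idm[, , , c]); pc <- as.vector(phi$inverse[, , , c])
    inner <- inner & co >= band & co <= d[c] - 1 - band &
      pc >= band & pc <= d[c] - 1 - band
  }
  if (!any(inner)) return(0)
  max(err[inner])
}

#' Integrate a velocity field into a diffeomorphism
#'
#' Semi-Lagrangian integration of the flow ODE `dphi_t/dt = v_t(phi_t)` over
#' `T` steps of size `1/T`; the inverse map is built by integrating `-v`
#' backward in time. Zero velocity yields the identity; a constant field `u`
#' approaches a translation by `u`.
#'
#' @param vf a [velocity_field].
#' @param check validate the resulting [diffeomorphism] (default TRUE).
#' @return A [diffeomorphism].
#' @export
integrate_flow <- function(vf, check = TRUE) {
  stopifnot(inherits(vf, "velocity_field"))
  d <- vf$dims
  dt <- 1 / vf$T
  idm <- identity_map(d)
  cx <- as.vector(idm[, , , 1]); cy <- as.vector(idm[, , , 2])
  cz <- as.vector(idm[, , , 3])
  # forward: particle positions phi_t(x), Euler steps along v_t
  fwd <- idm
  for (t in seq_len(vf$T)) {
    vv <- interp_field(vf$v[[t]], as.vector(fwd[, , , 1]),
                       as.vector(fwd[, , , 2]), as.vector(fwd[, , , 3]))
    for (c in 1:3) fwd[, , , c] <- fwd[, , , c] + dt * array(vv[, c], d)
  }
  # inverse: psi_t(x) = psi_{t-1}(x - dt * v_t(x)) so psi_T = phi^{-1}
  inv <- idm
  for (t in seq_len(vf$T)) {
    vt <- vf$v[[t]]
    bx <- cx - dt * as.vector(vt[, , , 1])
    by <- cy - dt * as.vector(vt[, , , 2])
    bz <- cz - dt * as.vector(vt[, , , 3])
    vals <- interp_field(inv, bx, by, bz)
    for (c in 1:3) inv[, , , c] <- array(vals[, c], d)
  }
  diffeomorphism(fwd, inv, check = check)
}

#' Warp an intensity volume through a diffeomorphism
#'
#' Linear interpolation at the inverse-pulled coordinates
#' (`out(x) = I(phi^-1(x))`), with edge clamping outside the grid. With the
#' registration convention (forward map sends atlas points toward the target)
#' this carries the atlas image onto the target lattice.
#'
#' @param volume an [intensity_volume].
#' @param phi a [diffeomorphism] on the same grid.
#' @return An [intensity_volume].
#' @export
warp_image <- function(volume, phi) {
  stopifnot(identical(volume$grid$dims, phi$dims))
  v <- cpp_interp3(volume$values, as.vector(phi$inverse[, , , 1]),
                   as.vector(phi$inverse[, , , 2]),
                   as.vector(phi$inverse[, , , 3]))
  intensity_volume(array(v, phi$dims), volume$grid)
}

#' Warp a label volume (hard labels or interpolated label prior)
#'
#' Mode `"nearest"` pulls hard labels back through `phi^-1` by
#' nearest-neighbour lookup. Mode `"prob"` linearly interpolates the one-hot
#' indicator of every label (background 0 included), returning per-voxel label
#' probabilities that sum to 1: voxels interior to a structure keep an
#' indicator (probability 1), and only boundary voxels get interpolated mass —
#' the label-prior rule of the fusion model.
#'
#' @param labels a [label_volume].
#' @param phi a [diffeomorphism] on the same grid.
#' @param mode `"nearest"` or `"prob"`.
#' @return `"nearest"`: a [label_volume]. `"prob"`: an object of class
#'   `label_prior` with fields `probs` (`(n1,n2,n3,L)` array), `label_ids`
#'   (integer vector of length `L`, first entry 0), `grid`, `dictionary`.
#' @export
warp_labels <- function(labels, phi, mode = c("nearest", "prob")) {
  mode <- match.arg(mode)
  stopifnot(identical(labels$grid$dims, phi$dims))
  ix <- as.vector(phi$inverse[, , , 1])
  iy <- as.vector(phi$inverse[, , , 2])
  iz <- as.vector(phi$inverse[, , , 3])
  if (mode == "nearest") {
    lab <- cpp_interp3_nn(labels$labels, ix, iy, iz)
    return(label_volume(array(lab, phi$dims), labels$grid, labels$dictionary))
  }
  ids <- sort(unique(c(0L, as.vector(labels$labels))))
  probs <- array(0, c(phi$dims, length(ids)))
  for (i in seq_along(ids)) {
    ind <- array(as.numeric(labels$labels == ids[i]), phi$dims)
    probs[, , , i] <- array(cpp_interp3(ind, ix, iy, iz), phi$dims)
  }
  structure(list(probs = probs, label_ids = ids, grid = labels$grid,
                 dictionary = labels$dictionary),
            class = "label_prior")
}
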