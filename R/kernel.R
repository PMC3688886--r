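#' Smoothing-operator parameters
#'
#' Parameters of the differential operator `L = (-alpha * laplacian + gamma)^p`
#' whose induced norm regularizes the velocity fields. The registration kernel
#' is `K = (L^T L)^{-1}`, applied in the discrete Fourier domain with
#' eigenvalues `(alpha * lap(w) + gamma)^(-2p)`, where `lap` is the symbol of
#' the standard 7-point discrete Laplacian.
#'
#' @param alpha,gamma positive reals weighting the Laplacian and identity parts.
#' @param p positive integer power of the operator (default 2).
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(alpha = 1, gamma = 1, p = 2L) {
  stopifnot(alpha > 0, gamma > 0, p >= 1)
  structure(list(alpha = alpha, gamma = gamma, p = as.integer(p)),
            class = "kernel_params")
}

# Symbol of the 7-point discrete Laplacian (unit voxel spacing), per axis
# frequency k = 0..n-1: 2 - 2*cos(2*pi*k/n); summed over axes on the grid.
laplacian_symbol <- function(dims) {
  lam <- function(n) 2 - 2 * cos(2 * pi * (seq_len(n) - 1) / n)
  l1 <- lam(dims[1]); l2 <- lam(dims[2]); l3 <- lam(dims[3])
  outer(outer(l1, l2, "+"), l3, "+")
}

# Eigenvalues of L^T L = (alpha*lap + gamma)^(2p) on the grid.
operator_symbol_sq <- function(dims, params) {
  (params$alpha * laplacian_symbol(dims) + params$gamma)^(2 * params$p)
}

#' Apply the registration smoothing kernel K = (L'L)^-1
#'
#' Applies the kernel per component in the Fourier domain (periodic
#' boundary). Linear and symmetric positive definite; a spatially constant
#' field `c` maps to `c / gamma^(2p)`.
#'
#' @param field a 3-D array, or a 4-D array whose last dimension indexes
#'   vector components.
#' @param params a [kernel_params].
#' @return An array of the same shape.
#' @export
kernel_apply <- function(field, params) {
  if (!all(is.finite(field))) stop("kernel_apply: non-finite input")
  d <- dim(field)
  if (length(d) == 3) {
    ksym <- 1 / operator_symbol_sq(d, params)
    return(Re(stats::fft(stats::fft(field) * ksym, inverse = TRUE)) / prod(d))
  }
  stopifnot(length(d) == 4)
  ksym <- 1 / operator_symbol_sq(d[1:3], params)
  out <- field
  for (c in seq_len(d[4])) {
    f <- array(field[, , , c], d[1:3])
    out[, , , c] <- Re(stats::fft(stats::fft(f) * ksym, inverse = TRUE)) / prod(d[1:3])
  }
  out
}

#' Time-indexed velocity field
#'
#' A list of `T` vector fields (each an `(n1, n2, n3, 3)` array, voxel units
#' per unit time) discretizing the flow velocity.
#'
#' @param v a single 4-D array or a list of 4-D arrays (one per timestep).
#' @return An object of class `velocity_field` with fields `v` (list), `T`,
#'   `dims`.
#' @export
velocity_field <- function(v) {
  if (is.array(v)) v <- list(v)
  stopifnot(length(v) >= 1)
  d <- dim(v[[1]])
  stopifnot(length(d) == 4, d[4] == 3)
  for (vt in v) {
    if (!identical(dim(vt), d)) stop("velocity_field: inconsistent timesteps")
    if (!all(is.finite(vt))) stop("velocity_field: non-finite components")
  }
  structure(list(v = v, T = length(v), dims = d[1:3]), class = "velocity_field")
}

zero_velocity <- function(dims, T) {
  velocity_field(rep(list(array(0, c(dims, 3))), T))
}

#' Geodesic energy of a velocity field
#'
#' `(1/T) * sum_t <L'L v_t, v_t>` evaluated by Fourier-domain quadrature
#' (Parseval). Non-negative, zero iff the field is identically zero, and
#' quadratic: `energy(2v) = 4 * energy(v)`. Serves as the squared metric
#' distance from the identity used by the transformation prior.
#'
#' @param vf a [velocity_field].
#' @param params a [kernel_params].
#' @return A non-negative scalar.
#' @export
geodesic_energy <- function(vf, params) {
  stopifnot(inherits(vf, "velocity_field"))
  a2 <- operator_symbol_sq(vf$dims, params)
  n <- prod(vf$dims)
  e <- 0
  for (vt in vf$v) {
    for (c in 1:3) {
      vh <- stats::fft(array(vt[, , , c], vf$dims))
      e <- e + sum(a2 * Mod(vh)^2) / n
    }
  }
  e / vf$T
}
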