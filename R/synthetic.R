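# Seeded generators: labeled phantoms emulating subcortical structures in a
# WM/GM/CSF background, and atlas populations obtained by random
# diffeomorphic deformation of a phantom. Everything is a pure function of
# (spec, seed); generators save and restore the caller's RNG state.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647L))
  force(expr)
}

#' Phantom specification
#'
#' Describes a labeled digital phantom: ellipsoidal structures (T1-like mean
#' intensities) embedded in a concentric WM / GM-shell / CSF-exterior
#' background. Each structure is a list with `name`, `center` (voxel coords),
#' `radii` (voxels) and `mean`; a structure may give `offset` instead of
#' `center`, placing it relative to the previous structure's center (touching
#' or adjacent structures). Later structures overwrite earlier ones where they
#' overlap.
#'
#' @param dims grid dimensions (default `c(48, 48, 48)`).
#' @param structures list of structure descriptions; `NULL` gives the default
#'   five-structure set (thalamus-, putamen-, caudate-, hippocampus-like gray
#'   structures plus a CSF-dark ventricle adjacent to the hippocampus).
#' @param tissue_means named means for the generic background tissues,
#'   ascending CSF < GM < WM (T1-weighted convention).
#' @param tissue_sds extra per-tissue intensity sd (default 0).
#' @param noise_sd additive Gaussian noise sd (default 4).
#' @param spacing voxel spacing in mm; the clinical default
#'   `c(0.9375, 0.9375, 1.2)`.
#' @param seed integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(48L, 48L, 48L), structures = NULL,
                         tissue_means = c(CSF = 30, GM = 80, WM = 110),
                         tissue_sds = c(CSF = 0, GM = 0, WM = 0),
                         noise_sd = 4, spacing = c(0.9375, 0.9375, 1.2),
                         seed = 1L) {
  dims <- as.integer(dims)
  if (is.null(structures)) structures <- default_structures(dims)
  stopifnot(length(structures) >= 1, noise_sd >= 0)
  prev_center <- NULL
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    if (is.null(s$center)) {
      if (is.null(s$offset) || is.null(prev_center)) {
        stop("structure ", i, " needs a center (or an offset after the first)")
      }
      s$center <- prev_center + s$offset
      structures[[i]] <- s
    }
    if (any(s$radii <= 0)) stop("structure radii must be positive")
    if (any(s$center - s$radii < 0) || any(s$center + s$radii > dims - 1)) {
      stop("structure '", s$name, "' does not fit within the grid")
    }
    prev_center <- s$center
  }
  structure(list(dims = dims, structures = structures,
                 tissue_means = tissue_means, tissue_sds = tissue_sds,
                 noise_sd = noise_sd, spacing = spacing,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Five structures at test scale: four gray-matter-like ellipsoids and one
# ventricle-like CSF-dark ellipsoid placed adjacent to the hippocampus-like
# structure (the hard boundary the generic-tissue labels help with).
default_structures <- function(dims) {
  c0 <- (dims - 1) / 2
  sc <- dims / 48
  list(
    list(name = "thalamus",    center = c0 + c(-9, 6, 0) * sc,
         radii = c(6, 5, 5) * sc, mean = 95),
    list(name = "putamen",     center = c0 + c(9, 6, 2) * sc,
         radii = c(5, 4, 5) * sc, mean = 88),
    list(name = "caudate",     center = c0 + c(8, -7, -2) * sc,
         radii = c(4, 5, 4) * sc, mean = 85),
    list(name = "hippocampus", center = c0 + c(-8, -8, 1) * sc,
         radii = c(5, 4, 4) * sc, mean = 75),
    list(name = "ventricle",   offset = c(7, 3, 0) * sc,
         radii = c(4, 4, 5) * sc, mean = 32)
  )
}

# ids: structures 1..K, then CSF/GM/WM = K+1..K+3 (ascending mean order).
phantom_label_ids <- function(spec) {
  K <- length(spec$structures)
  structure_ids <- stats::setNames(
    seq_len(K), vapply(spec$structures, `[[`, "", "name"))
  tissue_ids <- stats::setNames(K + 1:3, names(spec$tissue_means))
  list(structures = structure_ids, tissues = tissue_ids)
}

#' Generate a labeled phantom
#'
#' Rasterizes the spec's ellipsoids (membership `sum(((x - c) / r)^2) <= 1`)
#' into a structure label volume, lays down the WM/GM/CSF background, and adds
#' Gaussian noise. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec].
#' @return A list of class `phantom`: `image` ([intensity_volume]), `labels`
#'   (structure labels only), `full_labels` (structures plus generic tissue
#'   labels covering every voxel), `ids` (label id bookkeeping), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  grid <- voxel_grid(d, spec$spacing)
  ids <- phantom_label_ids(spec)
  co <- grid_coords(d)

  # concentric background: WM core, GM shell, CSF outside the "brain"
  c0 <- (d - 1) / 2
  R <- 0.45 * d
  rn <- colSums(((co - c0) / R)^2)
  tissue <- ifelse(rn > 1, ids$tissues[["CSF"]],
                   ifelse(rn > 0.64, ids$tissues[["GM"]], ids$tissues[["WM"]]))
  means <- stats::setNames(spec$tissue_means[names(ids$tissues)],
                           ids$tissues)
  intensity <- unname(means[as.character(tissue)])

  labels <- integer(prod(d))
  for (i in seq_along(spec$structures)) {
    s <- spec$structures[[i]]
    inside <- colSums(((co - s$center) / s$radii)^2) <= 1
    labels[inside] <- i
    intensity[inside] <- s$mean
  }
  full <- ifelse(labels > 0L, labels, tissue)

  intensity <- with_seed(spec$seed, {
    x <- intensity + stats::rnorm(length(intensity), 0, spec$noise_sd)
    for (tn in names(ids$tissues)) {
      sd_t <- spec$tissue_sds[[tn]]
      if (!is.null(sd_t) && is.finite(sd_t) && sd_t > 0) {
        sel <- full == ids$tissues[[tn]]
        x[sel] <- x[sel] + stats::rnorm(sum(sel), 0, sd_t)
      }
    }
    x
  })

  dict_struct <- stats::setNames(names(ids$structures), ids$structures)
  dict_full <- c(dict_struct, stats::setNames(names(ids$tissues), ids$tissues))
  structure(list(
    image = intensity_volume(array(intensity, d), grid),
    labels = label_volume(array(labels, d), grid, dict_struct),
    full_labels = label_volume(array(full, d), grid, dict_full),
    ids = ids, spec = spec
  ), class = "phantom")
}

#' Random diffeomorphism by smoothed-noise stationary flow
#'
#' Samples a white-noise vector field, smooths it with a Gaussian kernel of
#' width `smoothness` voxels, rescales so the largest velocity norm equals
#' `amplitude` voxels, and integrates it as a stationary velocity over
#' `steps >= 8` Euler steps. If the forward map's interior Jacobian
#' determinant is not everywhere positive the amplitude is halved and the map
#' rebuilt (up to 3 retries) before erroring.
#'
#' @param dims grid dimensions (or a [voxel_grid]).
#' @param amplitude maximum displacement scale in voxels (0 gives identity).
#' @param smoothness Gaussian smoothing width in voxels.
#' @param seed integer seed.
#' @param steps integration steps (default 8).
#' @return A [diffeomorphism].
#' @export
random_diffeomorphism <- function(dims, amplitude, smoothness, seed,
                                  steps = 8L) {
  if (inherits(dims, "voxel_grid")) dims <- dims$dims
  dims <- as.integer(dims)
  stopifnot(amplitude >= 0, smoothness > 0, steps >= 8)
  if (amplitude == 0) {
    idm <- identity_map(dims)
    return(diffeomorphism(idm, idm, check = FALSE))
  }
  raw <- with_seed(seed, array(stats::rnorm(prod(dims) * 3), c(dims, 3)))
  sm <- gaussian_smooth_field(raw, smoothness)
  vnorm <- sqrt(rowSums(matrix(sm, ncol = 3)^2))
  sm <- sm * (amplitude / max(vnorm))
  amp <- amplitude
  for (try in 0:3) {
    vf <- velocity_field(rep(list(sm * (amp / amplitude)), steps))
    phi <- integrate_flow(vf, check = FALSE)
    if (min_interior_jacobian(phi$forward) > 0) {
      return(diffeomorphism(phi$forward, phi$inverse, check = TRUE))
    }
    amp <- amp / 2
  }
  stop("random_diffeomorphism: invertibility not achieved after 3 retries")
}

# Periodic Gaussian smoothing of each component, width sigma voxels.
gaussian_smooth_field <- function(field, sigma) {
  d <- dim(field)[1:3]
  wsq <- function(n) {
    k <- seq_len(n) - 1
    w <- 2 * pi * ifelse(k <= n / 2, k, k - n) / n
    w^2
  }
  gsym <- exp(-0.5 * sigma^2 *
                (outer(outer(wsq(d[1]), wsq(d[2]), "+"), wsq(d[3]), "+")))
  out <- field
  for (c in 1:3) {
    f <- array(field[, , , c], d)
    out[, , , c] <- Re(stats::fft(stats::fft(f) * gsym, inverse = TRUE)) / prod(d)
  }
  out
}

#' Atlas population specification
#'
#' @param n_atlases number of atlases (default 5, the test-scale stand-in for
#'   a leave-one-out atlas set).
#' @param amplitude deformation amplitude in voxels (default 2).
#' @param smoothness deformation smoothness in voxels (default 6).
#' @param jitter_sd per-atlas global intensity offset sd (scanner/gain
#'   variation; default 2 intensity units).
#' @param seed integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_atlases = 5L, amplitude = 2, smoothness = 6,
                            jitter_sd = 2, seed = 1L) {
  stopifnot(n_atlases >= 1, amplitude >= 0, smoothness > 0, jitter_sd >= 0)
  structure(list(n_atlases = as.integer(n_atlases), amplitude = amplitude,
                 smoothness = smoothness, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a deformed atlas population from a phantom
#'
#' Each atlas is the phantom warped by an independent random diffeomorphism
#' (linear interpolation for the intensity image, nearest neighbour for both
#' label volumes) plus a per-atlas global intensity offset. The ground-truth
#' deformation is stored on each atlas for recovery tests.
#'
#' @param phantom a `phantom` from [generate_phantom()].
#' @param pop_spec a [population_spec].
#' @return A list of objects of class `atlas`, each with fields `id`, `image`,
#'   `labels` (structure charts), `full_labels` (structure + tissue charts),
#'   `truth_phi`, `jitter`.
#' @export
generate_population <- function(phantom, pop_spec) {
  stopifnot(inherits(phantom, "phantom"), inherits(pop_spec, "population_spec"))
  dims <- phantom$image$grid$dims
  lapply(seq_len(pop_spec$n_atlases), function(a) {
    seed_a <- (pop_spec$seed * 1009L + a * 7919L) %% 2147483647L
    phi <- random_diffeomorphism(dims, pop_spec$amplitude,
                                 pop_spec$smoothness, seed = seed_a)
    img <- warp_image(phantom$image, phi)
    jit <- with_seed(seed_a + 1L, stats::rnorm(1, 0, pop_spec$jitter_sd))
    img$values <- img$values + jit
    structure(list(
      id = a,
      image = img,
      labels = warp_labels(phantom$labels, phi, "nearest"),
      full_labels = warp_labels(phantom$full_labels, phi, "nearest"),
      truth_phi = phi,
      jitter = jit
    ), class = "atlas")
  })
}

#' @export
print.atlas <- function(x, ...) {
  cat("atlas", x$id, "on", paste(x$image$grid$dims, collapse = "x"),
      "grid; structure voxels:", sum(x$labels$labels > 0), "\n")
  invisible(x)
}

#' Deliberately corrupt an atlas (outlier-rejection fixtures)
#'
#' Modes: `"shift_labels"` translates both label volumes by `shift` voxels
#' along x while leaving the intensity image alone (labels no longer match the
#' anatomy); `"invert_contrast"` reverses the intensity scale and keeps
#' labels; `"large_warp"` applies an extra strong random deformation to image
#' and labels. Deterministic given `seed`.
#'
#' @param atlas an `atlas`.
#' @param mode one of `"shift_labels"`, `"invert_contrast"`, `"large_warp"`.
#' @param seed integer seed (used by `"large_warp"`).
#' @param shift voxel shift for `"shift_labels"` (default 6).
#' @return The corrupted `atlas`.
#' @export
corrupt_atlas <- function(atlas, mode, seed = 1L, shift = 6L) {
  stopifnot(inherits(atlas, "atlas"))
  if (!mode %in% c("shift_labels", "invert_contrast", "large_warp")) {
    stop("corrupt_atlas: unknown mode '", mode, "'")
  }
  out <- atlas
  if (mode == "shift_labels") {
    shift_arr <- function(lv) {
      d <- dim(lv$labels)
      new <- array(0L, d)
      src <- seq_len(d[1] - shift)
      new[src + shift, , ] <- lv$labels[src, , ]
      # keep background tissue coverage where full labels got shifted out
      if (length(lv$dictionary) && any(new == 0L)) {
        fill <- lv$labels[c(seq_len(shift), src), , ]
        new[new == 0L] <- fill[new == 0L]
      }
      label_volume(new, lv$grid, lv$dictionary)
    }
    out$labels <- {
      d <- dim(atlas$labels$labels)
      new <- array(0L, d)
      src <- seq_len(d[1] - shift)
      new[src + shift, , ] <- atlas$labels$labels[src, , ]
      label_volume(new, atlas$labels$grid, atlas$labels$dictionary)
    }
    out$full_labels <- shift_arr(atlas$full_labels)
  } else if (mode == "invert_contrast") {
    v <- atlas$image$values
    out$image <- intensity_volume(max(v) + min(v) - v, atlas$image$grid)
  } else {
    phi <- random_diffeomorphism(atlas$image$grid$dims, amplitude = 8,
                                 smoothness = 4, seed = seed)
    out$image <- warp_image(atlas$image, phi)
    out$labels <- warp_labels(atlas$labels, phi, "nearest")
    out$full_labels <- warp_labels(atlas$full_labels, phi, "nearest")
  }
  out$corrupted <- mode
  out
}
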