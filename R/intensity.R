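# Per-chart Gaussian intensity statistics (each atlas chart carries its own
# mean and variance), the conditionally Gaussian voxel log-likelihood, and
# the 3-class tissue mixture that supplies generic WM/GM/CSF labels.

#' Per-chart intensity statistics of an atlas
#'
#' Empirical mean and unbiased variance of the atlas intensity over each
#' labeled chart. Variances are clamped to a floor of
#' `max(1e-6, 0.01 * var(image))` so noise-free synthetic charts keep
#' non-degenerate likelihoods.
#'
#' @param image an [intensity_volume].
#' @param labels a [label_volume] on the same grid; every nonzero label needs
#'   at least one voxel.
#' @return An object of class `chart_stats`: data.frame with columns `label`,
#'   `mean`, `var`, `n`, plus attribute `floor`.
#' @export
estimate_chart_stats <- function(image, labels) {
  stopifnot(identical(image$grid$dims, labels$grid$dims))
  v <- as.vector(image$values)
  l <- as.vector(labels$labels)
  ids <- sort(unique(l[l > 0L]))
  if (!length(ids)) stop("estimate_chart_stats: no labeled voxels")
  floor_var <- max(1e-6, 0.01 * stats::var(v))
  rows <- lapply(ids, function(k) {
    x <- v[l == k]
    s2 <- if (length(x) > 1) stats::var(x) else 0
    data.frame(label = k, mean = mean(x), var = max(s2, floor_var),
               n = length(x))
  })
  out <- do.call(rbind, rows)
  attr(out, "floor") <- floor_var
  class(out) <- c("chart_stats", "data.frame")
  out
}

# log N(x; mu, s2), vectorized.
gaussian_loglik <- function(x, mu, s2) {
  -0.5 * log(2 * pi * s2) - (x - mu)^2 / (2 * s2)
}

#' Gaussian voxel log-likelihood under an atlas chart
#'
#' `log N(intensity; mu_{a,k}, sigma2_{a,k})` for chart (label) `k` of the
#' atlas whose [chart_stats][estimate_chart_stats] are supplied.
#'
#' @param intensity numeric vector of target intensities.
#' @param label chart label id (scalar).
#' @param stats a `chart_stats` object.
#' @return Numeric vector of log-densities.
#' @export
voxel_loglik <- function(intensity, label, stats) {
  i <- match(label, stats$label)
  if (is.na(i)) stop("voxel_loglik: label ", label, " absent from chart stats")
  gaussian_loglik(intensity, stats$mean[i], stats$var[i])
}

#' Fit a C-class Gaussian mixture to intensities
#'
#' EM from a deterministic k-means-style initialization (Lloyd iterations
#' seeded at equally spaced points over the intensity range, so a minority
#' tissue class cannot be missed when one class dominates the sample); the
#' data log-likelihood is non-decreasing over EM iterations and components
#' are reported sorted by mean (ascending - the CSF, GM, WM convention for
#' C = 3).
#'
#' @param x numeric intensity samples (at least `10 * C`).
#' @param C number of components (default 3).
#' @param seed kept for interface symmetry; the fit is deterministic.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return An object of class `tissue_gmm`: `weights`, `means`, `vars`,
#'   `loglik` (per-iteration trace), `C`.
#' @export
fit_tissue_gmm <- function(x, C = 3L, seed = 1L, max_iter = 200L, tol = 1e-8) {
  x <- as.numeric(x)
  if (length(x) < 10 * C) stop("fit_tissue_gmm: need at least ", 10 * C, " samples")
  if (stats::var(x) == 0) stop("fit_tissue_gmm: all intensities identical")
  floor_var <- max(1e-6, 1e-4 * stats::var(x))
  # deterministic Lloyd k-means from range-spread seeds
  mu <- min(x) + (2 * seq_len(C) - 1) / (2 * C) * (max(x) - min(x))
  for (it in seq_len(50)) {
    cl <- max.col(-abs(outer(x, mu, "-")), ties.method = "first")
    new_mu <- vapply(seq_len(C), function(c)
      if (any(cl == c)) mean(x[cl == c]) else mu[c], numeric(1))
    done <- max(abs(new_mu - mu)) < 1e-8
    mu <- new_mu
    if (done) break
  }
  s2 <- vapply(seq_len(C), function(c)
    if (sum(cl == c) > 1) stats::var(x[cl == c]) else floor_var, numeric(1))
  s2 <- pmax(s2, floor_var)
  w <- vapply(seq_len(C), function(c) max(mean(cl == c), 1e-3), numeric(1))
  w <- w / sum(w)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(C), function(c)
      log(w[c]) + gaussian_loglik(x, mu[c], s2[c]), numeric(length(x)))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    r <- exp(logd - lse)                     # responsibilities, rows sum to 1
    nk <- colSums(r)
    w <- nk / length(x)
    mu <- colSums(r * x) / nk
    s2 <- pmax(colSums(r * (outer(x, mu, "-")^2)) / nk, floor_var)
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll)) break
    ll_old <- ll
  }
  o <- order(mu)
  structure(list(weights = w[o], means = mu[o], vars = s2[o],
                 loglik = ll_trace, C = C),
            class = "tissue_gmm")
}

#' @export
print.tissue_gmm <- function(x, ...) {
  cat("tissue_gmm with", x$C, "components\n")
  print(data.frame(weight = signif(x$weights, 4), mean = signif(x$means, 5),
                   sd = signif(sqrt(x$vars), 4)))
  invisible(x)
}

# Posterior responsibilities of a fitted mixture at new points.
gmm_responsibilities <- function(gmm, x) {
  logd <- vapply(seq_len(gmm$C), function(c)
    log(gmm$weights[c]) + gaussian_loglik(x, gmm$means[c], gmm$vars[c]),
    numeric(length(x)))
  logd <- matrix(logd, nrow = length(x))
  m <- apply(logd, 1, max)
  exp(logd - (m + log(rowSums(exp(logd - m)))))
}

#' Generic WM/GM/CSF labeling of ROI voxels outside the structures
#'
#' Assigns each ROI voxel outside `structure_mask` to the tissue component
#' with the largest posterior responsibility under the fitted mixture, so
#' that every ROI voxel ends up labeled (structure or tissue). Exact ties go
#' to the lower label id.
#'
#' @param target an [intensity_volume].
#' @param box a [roi_box] on the target grid.
#' @param structure_mask logical 3-D array on the target grid (TRUE where a
#'   structure label already exists).
#' @param gmm a [tissue_gmm][fit_tissue_gmm] with `C` components.
#' @param tissue_ids integer label ids for the components in ascending-mean
#'   order (default `1:C`).
#' @param dictionary dictionary for the returned volume; defaults to
#'   CSF/GM/WM names for `C = 3`.
#' @return A [label_volume]: tissue ids inside the ROI outside the mask, 0
#'   elsewhere.
#' @export
label_generic_tissue <- function(target, box, structure_mask, gmm,
                                 tissue_ids = NULL, dictionary = NULL) {
  stopifnot(inherits(target, "intensity_volume"))
  check_box_in_grid(box, target$grid)
  if (is.null(tissue_ids)) tissue_ids <- seq_len(gmm$C)
  stopifnot(length(tissue_ids) == gmm$C)
  if (is.null(dictionary)) {
    nm <- if (gmm$C == 3) c("CSF", "GM", "WM") else paste0("tissue", seq_len(gmm$C))
    dictionary <- stats::setNames(nm, tissue_ids)
  }
  d <- target$grid$dims
  roi_mask <- array(FALSE, d)
  roi_mask[(box$lower[1] + 1):box$upper[1], (box$lower[2] + 1):box$upper[2],
           (box$lower[3] + 1):box$upper[3]] <- TRUE
  sel <- roi_mask & !structure_mask
  out <- array(0L, d)
  if (any(sel)) {
    r <- gmm_responsibilities(gmm, target$values[sel])
    best <- max.col(r, ties.method = "first")  # ties: lower component id
    out[sel] <- as.integer(tissue_ids[best])
  }
  label_volume(out, target$grid, dictionary)
}
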