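# S3 methods for the fitted fusion object.

#' @export
print.likefuse_fit <- function(x, ...) {
  n_iter <- nrow(x$trace)
  cat("Multi-atlas likelihood-fusion segmentation\n")
  cat(sprintf("  atlases: %d (%d retained after outlier screen)\n",
              nrow(x$outliers), length(x$retained)))
  cat(sprintf("  ROI: %s voxels; labels: %d (%d structures)\n",
              prod(box_dims(x$roi)), length(x$label_ids),
              length(x$structure_ids)))
  cat(sprintf("  EM: %d iterations, %s (final changed fraction %.2g)\n",
              n_iter, if (x$converged) "converged" else "iteration cap hit",
              x$trace$changed[n_iter]))
  cat(sprintf("  fused objective: %.6g\n", x$trace$objective[n_iter]))
  invisible(x)
}

#' Summary of a likelihood-fusion fit
#'
#' Reports per-structure segmented volumes, per-atlas mean selector weights,
#' the outlier screen, and EM convergence.
#'
#' @param object a `likefuse_fit`.
#' @param ... unused.
#' @export
summary.likefuse_fit <- function(object, ...) {
  seg <- object$segmentation$labels
  vols <- vapply(object$label_ids, function(k) sum(seg == k), numeric(1))
  structure(list(
    volumes = data.frame(
      label = object$label_ids,
      name = unname(object$dictionary[as.character(object$label_ids)]),
      voxels = vols,
      structure = object$label_ids %in% object$structure_ids),
    mean_weights = data.frame(atlas = object$retained,
                              mean_weight = colMeans(object$weights)),
    outliers = object$outliers,
    iterations = nrow(object$trace),
    converged = object$converged,
    objective = object$trace$objective[nrow(object$trace)]
  ), class = "summary.likefuse_fit")
}

#' @export
print.summary.likefuse_fit <- function(x, ...) {
  cat("Segmented volumes (voxels):\n")
  print(x$volumes, row.names = FALSE)
  cat("\nMean selector weight per retained atlas:\n")
  print(x$mean_weights, row.names = FALSE)
  if (any(x$outliers$removed)) {
    cat("\nRemoved outlier atlases:",
        paste(x$outliers$atlas[x$outliers$removed], collapse = ", "), "\n")
  }
  cat(sprintf("\nEM: %d iterations, %s; fused objective %.6g\n",
              x$iterations, if (x$converged) "converged" else "not converged",
              x$objective))
  invisible(x)
}

#' Per-atlas mean selector weights
#'
#' The average, over ROI voxels, of each retained atlas's convex selector
#' weight - how much each atlas contributes to interpreting the target.
#'
#' @param object a `likefuse_fit`.
#' @param ... unused.
#' @return Named numeric vector over retained atlases.
#' @export
coef.likefuse_fit <- function(object, ...) {
  stats::setNames(colMeans(object$weights),
                  paste0("atlas", object$retained))
}

#' Plot the EM trace of a fusion fit
#'
#' Fused objective (non-decreasing) and fraction of voxels changing label per
#' EM iteration.
#'
#' @param x a `likefuse_fit`.
#' @param ... forwarded to [graphics::plot()].
#' @export
plot.likefuse_fit <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$iteration, tr$objective, type = "b", pch = 16,
                 xlab = "EM iteration", ylab = "fused objective",
                 main = "likelihood-fusion objective", ...)
  graphics::plot(tr$iteration, tr$changed, type = "b", pch = 16, log = "y",
                 xlab = "EM iteration", ylab = "changed voxel fraction",
                 main = "label changes")
  invisible(x)
}
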