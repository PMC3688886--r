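# Likelihood-fusion EM. The target ROI is modelled as a conditionally
# Gaussian random field given deformed atlas charts; a latent per-voxel atlas
# selector says which atlas generates each voxel. The E-step computes the
# selector's conditional mean (per-voxel convex atlas weights, from
# window-aggregated per-atlas log-likelihoods); the M-step maximizes the
# fused per-label scores. Internals work on the ROI lattice: per-atlas score
# matrices are (nvox x L), the selector is (nvox x N).

#' Fusion configuration
#'
#' @param max_iter EM iteration cap (default 100).
#' @param epsilon stop when the fraction of voxels changing label falls below
#'   this (default 1e-4).
#' @param lambda transformation-prior weight: each atlas contributes
#'   `-lambda * geodesic_energy` to its selector evidence (default 0; the
#'   mechanism is always wired in).
#' @param window selector aggregation radius r in voxels: atlas evidence at a
#'   voxel is the sum of its per-voxel log-likelihood over the (2r+1)^3 box
#'   clipped to the ROI (default 2, the chart-local vicinity).
#' @param outlier_c robust cut multiplier: atlases scoring below
#'   `mean - outlier_c * sd` in mean Dice against the initialization are
#'   removed (default 1.5), always retaining at least `max(1, ceiling(N/2))`.
#' @param remove_outliers run the outlier screen when N >= 2 (default TRUE).
#' @param atlas_prior prior over atlases, `NULL` for uniform over retained.
#' @param roi_margin ROI dilation in voxels around the union of warped
#'   structure labels (default 4).
#' @param prior_floor floor for log label-prior terms (default -30 nats).
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(max_iter = 100L, epsilon = 1e-4, lambda = 0,
                          window = 2L, outlier_c = 1.5, remove_outliers = TRUE,
                          atlas_prior = NULL, roi_margin = 4L,
                          prior_floor = -30) {
  stopifnot(max_iter >= 1, epsilon > 0, lambda >= 0, window >= 0,
            outlier_c > 0, roi_margin >= 0, prior_floor < 0)
  structure(list(max_iter = as.integer(max_iter), epsilon = epsilon,
                 lambda = lambda, window = as.integer(window),
                 outlier_c = outlier_c, remove_outliers = remove_outliers,
                 atlas_prior = atlas_prior, roi_margin = as.integer(roi_margin),
                 prior_floor = prior_floor),
            class = "fusion_config")
}

#' Initialize the segmentation by majority vote over propagated labels
#'
#' Per-voxel argmax of the atlas-averaged label prior; exact ties go to the
#' lowest label id.
#'
#' @param priors list (one per atlas) of `(nvox x L)` label-prior matrices
#'   with identical column order.
#' @return Integer vector of column indices (1..L) per voxel.
#' @export
initialize_segmentation <- function(priors) {
  stopifnot(length(priors) >= 1)
  avg <- Reduce(`+`, priors) / length(priors)
  max.col(avg, ties.method = "first")
}

#' Per-voxel log-likelihood of the target under one atlas
#'
#' `l_a(x) = log N(I(x); mu_{a,W(x)}, sigma2_{a,W(x)}) + log pi_a(W(x)|x)`
#' with zero-probability priors floored. Computed by indexing a precomputed
#' score matrix; `score_matrix()` builds it.
#'
#' @param scores `(nvox x L)` per-label score matrix for the atlas.
#' @param w integer vector of current label column indices per voxel.
#' @return Numeric vector `l_a` over the ROI.
#' @export
atlas_loglik_field <- function(scores, w) {
  scores[cbind(seq_along(w), w)]
}

#' Per-label score matrix of one atlas over the ROI
#'
#' Gaussian chart log-likelihood plus floored log label-prior for every
#' candidate label. Labels missing from the atlas's chart stats contribute
#' the floor in place of the Gaussian term.
#'
#' @param intensities target intensities over the ROI (length nvox).
#' @param stats the atlas's [chart_stats][estimate_chart_stats].
#' @param prior `(nvox x L)` label-prior matrix for the atlas.
#' @param label_ids integer ids for the L columns.
#' @param floor log-prior floor in nats (default -30).
#' @return `(nvox x L)` matrix.
#' @export
score_matrix <- function(intensities, stats, prior, label_ids, floor = -30) {
  L <- length(label_ids)
  out <- matrix(floor, length(intensities), L)
  for (j in seq_len(L)) {
    i <- match(label_ids[j], stats$label)
    if (!is.na(i)) {
      out[, j] <- gaussian_loglik(intensities, stats$mean[i], stats$var[i])
    }
  }
  out + pmax(log(prior), floor)
}

#' Log transformation prior of a registered atlas
#'
#' The metric-distance weighting of solutions: `-lambda * geodesic_energy`
#' of the optimized velocity field (0 for identity registrations or
#' `lambda = 0`).
#'
#' @param fit an `lddmm_fit` or a [velocity_field].
#' @param kernel a [kernel_params] (used when `fit` is a velocity field).
#' @param lambda non-negative weight.
#' @return A scalar log-prior.
#' @export
transformation_log_prior <- function(fit, kernel = kernel_params(),
                                     lambda = 0) {
  if (lambda == 0) return(0)
  e <- if (inherits(fit, "lddmm_fit")) fit$energy
       else geodesic_energy(fit, kernel)
  -lambda * e
}

#' Atlas-selector conditional means (E-step)
#'
#' For each voxel, each atlas's evidence is its per-voxel log-likelihood
#' summed over the clipped box window of radius `r`, plus its transformation
#' log-prior and log atlas prior; weights are the numerically safe softmax
#' across atlases. Rows are convex: non-negative, summing to 1.
#'
#' @param loglik_fields list (per atlas) of per-voxel log-likelihood vectors.
#' @param dims ROI lattice dimensions (the vectors are in array order).
#' @param r aggregation radius in voxels.
#' @param log_priors per-atlas scalars (transformation log-prior plus log
#'   atlas prior); default 0.
#' @return `(nvox x N)` weight matrix; attribute `"evidence"` holds the
#'   aggregated per-atlas evidence used for the fused objective.
#' @export
compute_selector <- function(loglik_fields, dims, r = 2L, log_priors = NULL) {
  N <- length(loglik_fields)
  stopifnot(N >= 1)
  if (is.null(log_priors)) log_priors <- rep(0, N)
  stopifnot(length(log_priors) == N)
  nvox <- prod(dims)
  ev <- matrix(0, nvox, N)
  for (a in seq_len(N)) {
    f <- array(loglik_fields[[a]], dims)
    ev[, a] <- as.vector(cpp_boxsum3(f, as.integer(r))) + log_priors[a]
  }
  m <- do.call(pmax, lapply(seq_len(N), function(a) ev[, a]))
  q <- exp(ev - m)
  q <- q / rowSums(q)
  attr(q, "evidence") <- ev
  q
}

#' Fused per-voxel per-label scores (likelihood-fusion equation)
#'
#' Convex combination of the per-atlas per-label scores,
#' `S(x,k) = sum_a qbar(x,a) * score_a(x,k)`. The combination weights `qbar`
#' are the selector weights smoothed by the same clipped box window used to
#' aggregate the evidence (box mean); this makes the label update the exact
#' maximization step of the windowed EM objective, so the fused objective
#' cannot decrease. With a single atlas, or weights constant across the
#' window, `qbar` equals `q` and the combination reduces to the plain convex
#' fusion.
#'
#' @param score_mats list (per atlas) of `(nvox x L)` score matrices.
#' @param weights `(nvox x N)` selector weights from [compute_selector()].
#' @param dims ROI lattice dimensions.
#' @param r window radius (must match the selector's).
#' @return `(nvox x L)` fused score matrix.
#' @export
fused_label_scores <- function(score_mats, weights, dims, r = 2L) {
  N <- length(score_mats)
  stopifnot(ncol(weights) == N)
  nvox <- prod(dims)
  counts <- as.vector(cpp_boxsum3(array(1, dims), as.integer(r)))
  S <- matrix(0, nvox, ncol(score_mats[[1]]))
  for (a in seq_len(N)) {
    qb <- as.vector(cpp_boxsum3(array(weights[, a], dims), as.integer(r))) / counts
    S <- S + qb * score_mats[[a]]
  }
  S
}

#' Maximize the fused scores into a segmentation (M-step)
#'
#' Per-voxel argmax over labels; exact ties are broken toward the label with
#' the larger summed prior mass at that voxel, then the lowest label id.
#'
#' @param scores `(nvox x L)` fused score matrix.
#' @param prior_mass optional `(nvox x L)` summed label-prior mass for the
#'   tie-break.
#' @return Integer vector of label column indices.
#' @export
maximize_segmentation <- function(scores, prior_mass = NULL) {
  if (is.null(prior_mass)) return(max.col(scores, ties.method = "first"))
  n <- nrow(scores)
  best <- rep(1L, n)
  bs <- scores[, 1]
  bm <- prior_mass[, 1]
  for (j in seq_len(ncol(scores))[-1]) {
    sj <- scores[, j]; mj <- prior_mass[, j]
    take <- sj > bs | (sj == bs & mj > bm)
    best[take] <- j
    bs[take] <- sj[take]
    bm[take] <- mj[take]
  }
  best
}

#' Robust outlier-atlas removal
#'
#' Scores each atlas by the mean Dice overlap between its propagated hard
#' labels and the current segmentation across the structure labels, then
#' removes atlases scoring below `mean - c * sd`. At least
#' `max(1, ceiling(N/2))` atlases are always retained (best scores kept).
#'
#' @param seg integer label vector over the ROI (actual label ids).
#' @param warped_labels list (per atlas) of integer label vectors over the
#'   ROI.
#' @param structure_ids label ids entering the score.
#' @param c cut multiplier (default 1.5).
#' @return List: `retained` (atlas indices), `report` (data.frame with
#'   `atlas`, `score`, `removed`).
#' @export
remove_outlier_atlases <- function(seg, warped_labels, structure_ids,
                                   c = 1.5) {
  N <- length(warped_labels)
  if (N < 2) stop("remove_outlier_atlases: need at least 2 atlases")
  score <- vapply(warped_labels, function(w) {
    mean(vapply(structure_ids, function(k) dice_sets(seg == k, w == k),
                numeric(1)))
  }, numeric(1))
  m <- mean(score); s <- stats::sd(score)
  removed <- if (is.finite(s) && s > 0) score < m - c * s else rep(FALSE, N)
  keep_floor <- max(1L, ceiling(N / 2))
  if (sum(!removed) < keep_floor) {
    removed <- rep(TRUE, N)
    removed[order(score, decreasing = TRUE)[seq_len(keep_floor)]] <- FALSE
  }
  list(retained = which(!removed),
       report = data.frame(atlas = seq_len(N), score = score,
                           removed = removed))
}

# Dice between two logical vectors; both-empty convention = 1.
dice_sets <- function(a, b) {
  tp <- sum(a & b)
  den <- 2 * tp + sum(a & !b) + sum(!a & b)
  if (den == 0) 1 else 2 * tp / den
}

roi_indices <- function(box) {
  list(i = (box$lower[1] + 1):box$upper[1],
       j = (box$lower[2] + 1):box$upper[2],
       k = (box$lower[3] + 1):box$upper[3])
}

#' Multi-atlas segmentation by likelihood fusion
#'
#' The full pipeline: each atlas is registered to the target once by
#' [lddmm_match()] (the mode approximation: the optimized deformation stands
#' in for the integral over deformations and is reused across EM iterations);
#' atlas labels are propagated as hard labels and as interpolated label
#' priors over the cuboid ROI; per-chart Gaussian statistics are estimated in
#' each atlas's native space; outlier atlases are removed against the
#' majority-vote initialization; then the EM alternation (selector weights ->
#' fused scores -> segmentation argmax) runs until fewer than
#' `config$epsilon` of ROI voxels change label or `config$max_iter`
#' iterations. The monitored fused objective is non-decreasing; a decrease
#' beyond 1e-6 (relative) is a hard error.
#'
#' @param target an [intensity_volume].
#' @param atlases list of `atlas` objects (from [generate_population()]) or
#'   lists with fields `image` ([intensity_volume]) and `labels`
#'   ([label_volume]); the optional `full_labels` field carries structure
#'   plus generic-tissue charts.
#' @param reg_config a [registration_config].
#' @param config a [fusion_config].
#' @param kernel a [kernel_params].
#' @param registrations optional precomputed list of `lddmm_fit`s (one per
#'   atlas), e.g. to share registrations between fusion variants.
#' @param tissue_charts use `full_labels` (structure + WM/GM/CSF charts) when
#'   present (default TRUE); `FALSE` fuses structure charts only.
#' @param verbose print per-iteration progress.
#' @return An object of class `likefuse_fit`; see [print.likefuse_fit()].
#'   Key fields: `segmentation` (full-grid [label_volume]), `roi`,
#'   `weights` (`nvox x N` selector matrix over retained atlases), `trace`
#'   (per-iteration objective, Q value, changed fraction and selector
#'   convexity diagnostics), `weight_trace` (per-iteration per-atlas mean
#'   selector weight), `outliers`,
#'   `registrations`, `label_ids`, `dictionary`.
#' @export
likelihood_fusion <- function(target, atlases,
                              reg_config = registration_config(),
                              config = fusion_config(),
                              kernel = kernel_params(),
                              registrations = NULL,
                              tissue_charts = TRUE,
                              verbose = FALSE) {
  stopifnot(inherits(target, "intensity_volume"), length(atlases) >= 1)
  N <- length(atlases)
  pick_labels <- function(a) {
    if (tissue_charts && !is.null(a$full_labels)) a$full_labels else a$labels
  }
  for (a in atlases) {
    if (!grid_equal(a$image$grid, target$grid)) {
      stop("likelihood_fusion: atlas and target grids differ; resample first")
    }
  }

  # (1) optimized mappings, once per atlas (mode approximation)
  if (is.null(registrations)) {
    registrations <- lapply(atlases, function(a) {
      lddmm_match(a$image, target, reg_config, kernel, verbose = verbose)
    })
  }
  stopifnot(length(registrations) == N)

  # (2) propagate labels, compute ROI over warped structure labels
  warped_struct <- lapply(seq_len(N), function(a) {
    warp_labels(atlases[[a]]$labels, registrations[[a]]$phi, "nearest")
  })
  box <- compute_roi(warped_struct, margin_vox = config$roi_margin)
  rd <- box_dims(box)
  nvox <- prod(rd)
  idx <- roi_indices(box)
  tgt_roi <- as.vector(target$values[idx$i, idx$j, idx$k])

  # label universe: union of used (possibly tissue-augmented) chart labels
  used_labels <- lapply(atlases, pick_labels)
  lab_ids <- sort(unique(unlist(lapply(used_labels, function(l)
    setdiff(unique(as.vector(l$labels)), 0L)))))
  L <- length(lab_ids)
  dict <- character()
  for (l in used_labels) dict <- c(dict, l$dictionary)
  dict <- dict[!duplicated(names(dict))]
  structure_ids <- sort(unique(unlist(lapply(atlases, function(a)
    setdiff(unique(as.vector(a$labels$labels)), 0L)))))

  # per-atlas priors and hard labels on the ROI
  roi_coords <- local({
    idm <- identity_map(rd)
    list(x = as.vector(idm[, , , 1]) + box$lower[1],
         y = as.vector(idm[, , , 2]) + box$lower[2],
         z = as.vector(idm[, , , 3]) + box$lower[3])
  })
  priors <- vector("list", N)
  hard <- vector("list", N)
  for (a in seq_len(N)) {
    inv <- registrations[[a]]$phi$inverse
    px <- cpp_interp3(array(inv[, , , 1], dim(inv)[1:3]), roi_coords$x,
                      roi_coords$y, roi_coords$z)
    py <- cpp_interp3(array(inv[, , , 2], dim(inv)[1:3]), roi_coords$x,
                      roi_coords$y, roi_coords$z)
    pz <- cpp_interp3(array(inv[, , , 3], dim(inv)[1:3]), roi_coords$x,
                      roi_coords$y, roi_coords$z)
    lab_arr <- used_labels[[a]]$labels
    P <- matrix(0, nvox, L)
    for (j in seq_len(L)) {
      ind <- array(as.numeric(lab_arr == lab_ids[j]), dim(lab_arr))
      P[, j] <- cpp_interp3(ind, px, py, pz)
    }
    # rows sum to 1 minus the interpolated background mass; candidate labels
    # with no support at a voxel keep prior 0 (floored in the log domain)
    priors[[a]] <- P
    hard[[a]] <- cpp_interp3_nn(lab_arr, px, py, pz)
  }

  # (3) chart statistics (native atlas space), score matrices
  stats_list <- lapply(seq_len(N), function(a)
    estimate_chart_stats(atlases[[a]]$image, used_labels[[a]]))
  scores <- lapply(seq_len(N), function(a)
    score_matrix(tgt_roi, stats_list[[a]], priors[[a]], lab_ids,
                 floor = config$prior_floor))
  missing_charts <- unlist(lapply(seq_len(N), function(a) {
    miss <- setdiff(lab_ids, stats_list[[a]]$label)
    if (length(miss)) paste0("atlas ", a, ": labels ",
                             paste(miss, collapse = ","), " scored at floor")
    else character()
  }))

  # (4) initialization and outlier screen
  W <- initialize_segmentation(priors)
  outliers <- list(retained = seq_len(N),
                   report = data.frame(atlas = seq_len(N), score = NA_real_,
                                       removed = FALSE))
  if (config$remove_outliers && N >= 2) {
    outliers <- remove_outlier_atlases(
      lab_ids[W], hard, structure_ids, c = config$outlier_c)
  }
  keep <- outliers$retained
  Nk <- length(keep)
  atlas_prior <- config$atlas_prior
  if (is.null(atlas_prior)) atlas_prior <- rep(1 / Nk, Nk)
  stopifnot(length(atlas_prior) == Nk, all(atlas_prior > 0))
  atlas_prior <- atlas_prior / sum(atlas_prior)
  log_priors <- vapply(seq_along(keep), function(i) {
    log(atlas_prior[i]) +
      transformation_log_prior(registrations[[keep[i]]], kernel,
                               config$lambda)
  }, numeric(1))
  prior_mass <- Reduce(`+`, priors[keep])

  # re-initialize over retained atlases only
  W <- initialize_segmentation(priors[keep])

  # (5) EM alternation
  trace <- list()
  weight_trace <- list()
  obj_prev <- -Inf
  q <- matrix(1 / Nk, nvox, Nk)
  for (it in seq_len(config$max_iter)) {
    ll_fields <- lapply(keep, function(a) atlas_loglik_field(scores[[a]], W))
    q <- compute_selector(ll_fields, rd, r = config$window,
                          log_priors = log_priors)
    ev <- attr(q, "evidence")
    mx <- do.call(pmax, lapply(seq_len(Nk), function(a) ev[, a]))
    objective <- sum(mx + log(rowSums(exp(ev - mx))))
    S <- fused_label_scores(scores[keep], q, rd, r = config$window)
    W_new <- maximize_segmentation(S, prior_mass)
    q_value <- sum(S[cbind(seq_len(nvox), W_new)])
    changed <- mean(W_new != W)
    trace[[it]] <- data.frame(iteration = it, objective = objective,
                              q_value = q_value, changed = changed,
                              q_rowsum_err = max(abs(rowSums(q) - 1)),
                              q_min = min(q))
    weight_trace[[it]] <- colMeans(q)
    if (verbose) {
      message(sprintf("EM it %d: objective %.6g, changed %.5f",
                      it, objective, changed))
    }
    if (objective < obj_prev - 1e-6 * max(1, abs(obj_prev))) {
      stop("likelihood_fusion: fused objective decreased (",
           obj_prev, " -> ", objective, "); invariant violation")
    }
    obj_prev <- objective
    W <- W_new
    if (changed < config$epsilon) break
  }

  seg_roi <- label_volume(array(lab_ids[W], rd),
                          crop(target, box)$grid, dict)
  seg_full <- uncrop(seg_roi, box, target$grid, fill = 0L)
  structure(list(
    segmentation = seg_full,
    roi = box,
    weights = q,
    retained = keep,
    outliers = outliers$report,
    trace = do.call(rbind, trace),
    weight_trace = do.call(rbind, weight_trace),
    registrations = registrations,
    label_ids = lab_ids,
    structure_ids = structure_ids,
    dictionary = dict,
    notes = missing_charts,
    config = config,
    reg_config = reg_config,
    kernel = kernel,
    tissue_charts = tissue_charts,
    converged = length(trace) < config$max_iter ||
      trace[[length(trace)]]$changed < config$epsilon,
    call = match.call()
  ), class = "likefuse_fit")
}
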