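# Dice overlap evaluation and the Monte Carlo permutation (randomization)
# test used for group comparisons.

#' Dice overlap for one structure
#'
#' `2TP / (2TP + FP + FN)` between the automated and gold-standard voxel sets
#' of label `k`. When both sets are empty the score is 1 by convention
#' (flagged in [dice_table()] output).
#'
#' @param auto,gold [label_volume]s on one grid.
#' @param k label id present in both dictionaries.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(auto, gold, k) {
  if (!identical(auto$grid$dims, gold$grid$dims)) {
    stop("dice: volumes on different grids")
  }
  dice_sets(auto$labels == k, gold$labels == k)
}

#' Per-structure overlap table
#'
#' One row per requested label with Dice, TP/FP/FN voxel counts and both
#' volumes. Counts are conserved: `TP + FN` equals the gold volume and
#' `TP + FP` the automated volume.
#'
#' @inheritParams dice
#' @param labels integer label ids to tabulate (default: gold dictionary).
#' @return A data.frame of class `dice_table` with columns `label`, `name`,
#'   `dice`, `TP`, `FP`, `FN`, `auto_vol`, `gold_vol`, `both_empty`.
#' @export
dice_table <- function(auto, gold, labels = NULL) {
  if (is.null(labels)) labels <- as.integer(names(gold$dictionary))
  rows <- lapply(labels, function(k) {
    a <- auto$labels == k; g <- gold$labels == k
    tp <- sum(a & g); fp <- sum(a & !g); fn <- sum(!a & g)
    data.frame(label = k,
               name = if (as.character(k) %in% names(gold$dictionary))
                 gold$dictionary[[as.character(k)]] else NA_character_,
               dice = if (2 * tp + fp + fn == 0) 1 else
                 2 * tp / (2 * tp + fp + fn),
               TP = tp, FP = fp, FN = fn,
               auto_vol = tp + fp, gold_vol = tp + fn,
               both_empty = (tp + fp + fn) == 0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dice_table", "data.frame")
  out
}

welch_t <- function(a, b) {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  if (va + vb == 0) stop("degenerate groups: zero variance")
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Randomization test on two groups (Fisher's method)
#'
#' Computes the Welch t-statistic on the true split, then draws `n_perm`
#' uniformly random relabelings of the pooled values and reports
#' `p = (#{|t_perm| >= |t_obs|} + 1) / (n_perm + 1)` (add-one smoothing
#' prevents a Monte Carlo zero; the absolute-value convention makes the test
#' two-sided). `exact = TRUE` enumerates every split of the pooled values
#' instead and returns the unsmoothed exact fraction.
#'
#' @param groupA,groupB numeric vectors (each at least 2 values).
#' @param n_perm number of random permutations (default 10000).
#' @param seed integer seed; fixed seed gives bit-reproducible p-values.
#' @param exact enumerate all `choose(nA+nB, nA)` splits (small groups only).
#' @return List of class `perm_test`: `p`, `t_obs`, `n_perm`, `exact`.
#' @export
permutation_test <- function(groupA, groupB, n_perm = 10000L, seed = 1L,
                             exact = FALSE) {
  stopifnot(length(groupA) >= 2, length(groupB) >= 2, n_perm >= 1)
  t_obs <- welch_t(groupA, groupB)
  pool <- c(groupA, groupB)
  nA <- length(groupA)
  if (exact) {
    splits <- utils::combn(length(pool), nA)
    tt <- apply(splits, 2, function(ix) {
      tryCatch(welch_t(pool[ix], pool[-ix]), error = function(e) Inf)
    })
    p <- mean(abs(tt) >= abs(t_obs) - 1e-12)
    return(structure(list(p = p, t_obs = t_obs, n_perm = ncol(splits),
                          exact = TRUE), class = "perm_test"))
  }
  count <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      ix <- sample.int(length(pool), nA)
      tp <- tryCatch(welch_t(pool[ix], pool[-ix]), error = function(e) Inf)
      if (abs(tp) >= abs(t_obs) - 1e-12) hits <- hits + 1L
    }
    hits
  })
  structure(list(p = (count + 1) / (n_perm + 1), t_obs = t_obs,
                 n_perm = n_perm, exact = FALSE), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("randomization test: t = %.4f, p = %.5g (%s, %d %s)\n",
              x$t_obs, x$p, if (x$exact) "exact" else "Monte Carlo",
              x$n_perm, if (x$exact) "splits" else "permutations"))
  invisible(x)
}

#' Single-atlas versus multi-atlas comparison harness
#'
#' For each target fixture: runs the full fusion and, reusing the same
#' registrations, every single-atlas MAP segmentation; tabulates per-structure
#' Dice against the gold labels, and (given at least two targets) a
#' randomization-test p-value per structure between the single-atlas and
#' fusion Dice sets.
#'
#' @param targets list of lists with fields `image` ([intensity_volume]) and
#'   `gold` ([label_volume], structure labels).
#' @param atlases_list list (per target) of atlas lists, or a single atlas
#'   list reused for every target.
#' @param reg_config,config,kernel forwarded to [likelihood_fusion()].
#' @param tissue_charts forwarded to [likelihood_fusion()].
#' @param n_perm,seed randomization-test parameters.
#' @return List of class `single_multi_report`: `dice` (long data.frame with
#'   columns `target`, `method`, `atlas`, `label`, `name`, `dice`) and
#'   `pvalues` (per-structure data.frame, NA when too few targets).
#' @export
compare_single_vs_multi <- function(targets, atlases_list,
                                    reg_config = registration_config(),
                                    config = fusion_config(),
                                    kernel = kernel_params(),
                                    tissue_charts = TRUE,
                                    n_perm = 10000L, seed = 1L) {
  if (!is.null(atlases_list[[1]]$image)) {
    atlases_list <- rep(list(atlases_list), length(targets))
  }
  stopifnot(length(atlases_list) == length(targets),
            length(atlases_list[[1]]) >= 2)
  rows <- list()
  for (ti in seq_along(targets)) {
    tg <- targets[[ti]]
    atl <- atlases_list[[ti]]
    fit <- likelihood_fusion(tg$image, atl, reg_config, config, kernel,
                             tissue_charts = tissue_charts)
    sids <- fit$structure_ids
    dt <- dice_table(fit$segmentation, tg$gold, sids)
    rows[[length(rows) + 1]] <- data.frame(
      target = ti, method = "fusion", atlas = NA_integer_,
      label = dt$label, name = dt$name, dice = dt$dice)
    for (a in seq_along(atl)) {
      sfit <- likelihood_fusion(tg$image, atl[a], reg_config, config, kernel,
                                registrations = fit$registrations[a],
                                tissue_charts = tissue_charts)
      dt1 <- dice_table(sfit$segmentation, tg$gold, sids)
      rows[[length(rows) + 1]] <- data.frame(
        target = ti, method = "single", atlas = a,
        label = dt1$label, name = dt1$name, dice = dt1$dice)
    }
  }
  long <- do.call(rbind, rows)
  pv <- lapply(sort(unique(long$label)), function(k) {
    s <- long$dice[long$method == "single" & long$label == k]
    f <- long$dice[long$method == "fusion" & long$label == k]
    p <- if (length(f) >= 2 && length(s) >= 2) {
      tryCatch(permutation_test(f, s, n_perm = n_perm, seed = seed)$p,
               error = function(e) NA_real_)
    } else NA_real_
    data.frame(label = k, p = p, mean_single = mean(s), mean_fusion = mean(f))
  })
  structure(list(dice = long, pvalues = do.call(rbind, pv)),
            class = "single_multi_report")
}
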