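# Shared fixtures. Standard-fixture runs (48^3 grid, 5 structures, 5 atlases)
# are expensive, so each seed is computed once and memoised; only lightweight
# summaries are kept. Registration uses a scaled-down config (T = 2, two
# cascade stages, 4 iterations each) to fit the single-CPU test budget; the
# package defaults are exercised separately on a small pair.

.fixture_cache <- new.env(parent = emptyenv())

fast_reg_config <- function(max_iter = 4L) {
  registration_config(T = 2L, max_iter = max_iter, cascade = c(1, 0.1))
}

small_phantom <- function(dims = 32, noise_sd = 3, seed = 1) {
  generate_phantom(phantom_spec(dims = rep(dims, 3), noise_sd = noise_sd,
                                seed = seed))
}

# One standard-fixture seed: full fusion, all single-atlas MAP runs (shared
# registrations), and the no-tissue-chart arm. Returns summaries only.
standard_fixture_run <- function(seed) {
  key <- paste0("std", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  ph <- generate_phantom(phantom_spec(seed = seed))
  pop <- generate_population(ph, population_spec(seed = seed + 1000L))
  sids <- seq_along(ph$spec$structures)
  fit <- likelihood_fusion(ph$image, pop, fast_reg_config(), fusion_config(),
                           kernel_params())
  singles <- lapply(seq_along(pop), function(a) {
    sf <- likelihood_fusion(ph$image, pop[a], fast_reg_config(),
                            fusion_config(), kernel_params(),
                            registrations = fit$registrations[a])
    dice_table(sf$segmentation, ph$labels, sids)$dice
  })
  fit_nt <- likelihood_fusion(ph$image, pop, fast_reg_config(),
                              fusion_config(), kernel_params(),
                              registrations = fit$registrations,
                              tissue_charts = FALSE)
  reg_dice <- lapply(seq_along(pop), function(a) {
    w <- warp_labels(pop[[a]]$labels, fit$registrations[[a]]$phi, "nearest")
    list(pre = vapply(sids, function(k) dice(pop[[a]]$labels, ph$labels, k),
                      numeric(1)),
         post = vapply(sids, function(k) dice(w, ph$labels, k), numeric(1)))
  })
  res <- list(
    seed = seed,
    structure_ids = sids,
    structure_names = vapply(ph$spec$structures, `[[`, "", "name"),
    trace = fit$trace,
    weight_trace = fit$weight_trace,
    outliers = fit$outliers,
    dice_fusion = dice_table(fit$segmentation, ph$labels, sids)$dice,
    dice_singles = do.call(rbind, singles),      # atlas x structure
    dice_no_tissue = dice_table(fit_nt$segmentation, ph$labels, sids)$dice,
    trace_no_tissue = fit_nt$trace,
    reg_dice = reg_dice,
    reg_traces = lapply(fit$registrations, function(r) r$trace),
    chart_means = lapply(seq_along(pop), function(a) {
      st <- estimate_chart_stats(pop[[a]]$image, pop[[a]]$labels)
      st$truth <- vapply(st$label, function(k)
        ph$spec$structures[[k]]$mean + pop[[a]]$jitter, numeric(1))
      st
    }),
    phantom_stats = estimate_chart_stats(ph$image, ph$labels),
    phantom_truth = vapply(ph$spec$structures, `[[`, numeric(1), "mean"),
    phantom_noise_sd = ph$spec$noise_sd
  )
  .fixture_cache[[key]] <- res
  res
}

standard_fixture_seeds <- function(n = 10) seq_len(n)
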