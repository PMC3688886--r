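# Fusion EM components and the full pipeline's reductions/invariances.

test_that("initialization is the majority vote over propagated priors", {
  # 3 atlases, 2 vote label 2 at voxel 1; single/agreeing cases
  p1 <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)  # voxel1 -> k2, voxel2 -> k1
  p2 <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE)
  p3 <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)
  expect_identical(initialize_segmentation(list(p1)), c(2L, 1L))
  expect_identical(initialize_segmentation(list(p1, p1)), c(2L, 1L))
  expect_identical(initialize_segmentation(list(p1, p2, p3)), c(2L, 1L))
  # exact tie goes to the lowest column
  expect_identical(initialize_segmentation(list(p1, p3)), c(1L, 1L))
  expect_error(initialize_segmentation(list()))
})

test_that("score fields match a naive per-voxel loop (oracle)", {
  ph <- small_phantom(dims = 16, noise_sd = 3, seed = 51)
  atlas <- generate_population(ph, population_spec(n_atlases = 1, amplitude = 1,
                                                   smoothness = 4, seed = 52))[[1]]
  idm <- likefuse:::identity_map(c(16, 16, 16))
  phi <- diffeomorphism(idm, idm, check = FALSE)    # identity mapping
  pr <- warp_labels(atlas$full_labels, phi, "prob")
  st <- estimate_chart_stats(atlas$image, atlas$full_labels)
  ids <- sort(unique(as.vector(atlas$full_labels$labels)))
  ids <- setdiff(ids, 0L)
  P <- matrix(0, 16^3, length(ids))
  for (j in seq_along(ids)) {
    P[, j] <- as.vector(pr$probs[, , , which(pr$label_ids == ids[j])])
  }
  sc <- score_matrix(as.vector(ph$image$values), st, P, ids, floor = -30)
  W <- initialize_segmentation(list(P))
  ell <- atlas_loglik_field(sc, W)
  # naive double loop over a voxel subset
  set.seed(1)
  vox <- sample(16^3, 300)
  iv <- as.vector(ph$image$values)
  for (x in vox) {
    k <- ids[W[x]]
    mu <- st$mean[st$label == k]; s2 <- st$var[st$label == k]
    gauss <- -0.5 * log(2 * pi * s2) - (iv[x] - mu)^2 / (2 * s2)
    expect_equal(ell[x], gauss + max(log(P[x, W[x]]), -30), tolerance = 1e-10)
  }
  # full-ROI sum agrees with the naive accumulation
  naive_sum <- 0
  for (x in seq_len(16^3)) {
    k <- ids[W[x]]
    mu <- st$mean[st$label == k]; s2 <- st$var[st$label == k]
    naive_sum <- naive_sum - 0.5 * log(2 * pi * s2) -
      (iv[x] - mu)^2 / (2 * s2) + max(log(P[x, W[x]]), -30)
  }
  expect_equal(sum(ell), naive_sum, tolerance = 1e-8)
})

test_that("transformation prior scales with lambda and energy", {
  d <- c(12, 12, 12)
  kp <- kernel_params()
  v <- array(0, c(d, 3)); v[, , , 1] <- sin(2 * pi * (0:11) / 12)
  vf <- velocity_field(v)
  expect_identical(transformation_log_prior(vf, kp, 0), 0)
  expect_equal(transformation_log_prior(zero_velocity(d, 1), kp, 3), 0)
  lp1 <- transformation_log_prior(vf, kp, 2)
  expect_equal(lp1, -2 * geodesic_energy(vf, kp))
  expect_equal(transformation_log_prior(velocity_field(2 * v), kp, 2),
               4 * lp1, tolerance = 1e-10)
})

test_that("selector weights: symmetry, single atlas, dominance, convexity", {
  d <- c(6, 6, 6); n <- prod(d)
  set.seed(8)
  f <- rnorm(n)
  # identical atlases share the weight equally
  q <- compute_selector(list(f, f, f), d, r = 2)
  expect_equal(q, matrix(1 / 3, n, 3), ignore_attr = TRUE, tolerance = 1e-12)
  # single atlas -> weight 1
  q1 <- compute_selector(list(f), d, r = 2)
  expect_equal(q1, matrix(1, n, 1), ignore_attr = TRUE)
  # a >= 20-nat advantage forces the weight above 0.999
  q2 <- compute_selector(list(f + 20 / 125, f), d, r = 2)  # box holds 125 voxels
  inner <- which(array(TRUE, d) & likefuse:::cpp_boxsum3(array(1, d), 2L) == 125)
  expect_true(all(q2[inner, 1] > 0.999))
  # convexity at every voxel for random fields
  q3 <- compute_selector(list(rnorm(n), rnorm(n), rnorm(n), rnorm(n)), d,
                         r = 1, log_priors = c(0, -1, 0.5, 0))
  expect_true(all(q3 >= 0))
  expect_lt(max(abs(rowSums(q3) - 1)), 1e-8)
})

test_that("fused scores reduce correctly for degenerate weights", {
  d <- c(5, 5, 5); n <- prod(d)
  set.seed(9)
  s1 <- matrix(rnorm(n * 3), n, 3)
  s2 <- matrix(rnorm(n * 3), n, 3)
  # single atlas: exact passthrough
  expect_equal(fused_label_scores(list(s1), matrix(1, n, 1), d, r = 2), s1)
  # degenerate weights (1, 0) ignore the second atlas
  w10 <- cbind(rep(1, n), rep(0, n))
  expect_equal(fused_label_scores(list(s1, s2), w10, d, r = 2), s1)
  # uniform weights give the arithmetic mean
  wu <- matrix(0.5, n, 2)
  expect_equal(fused_label_scores(list(s1, s2), wu, d, r = 0), (s1 + s2) / 2)
})

test_that("segmentation maximization applies the documented tie-breaks", {
  s <- rbind(c(1, 2, 0), c(3, 3, 1), c(2, 2, 2))
  pm <- rbind(c(1, 1, 1), c(0.2, 0.7, 0.1), c(0.3, 0.3, 0.3))
  w <- maximize_segmentation(s, pm)
  expect_identical(w, c(2L, 2L, 1L))  # dominant; prior-mass tie; full tie -> id
  expect_identical(maximize_segmentation(s), c(2L, 1L, 1L))
})

test_that("outlier removal: vacuous on identical atlases, floors retention", {
  seg <- rep(c(1L, 2L, 0L), each = 10)
  same <- rep(list(seg), 4)
  out <- remove_outlier_atlases(seg, same, structure_ids = c(1L, 2L))
  expect_identical(out$retained, 1:4)
  # N = 2: at most one removed even with a terrible atlas
  bad <- rev(seg)
  out2 <- remove_outlier_atlases(seg, list(seg, bad), structure_ids = c(1L, 2L))
  expect_gte(length(out2$retained), 1)
  expect_error(remove_outlier_atlases(seg, list(seg), 1L), "at least 2")
})

test_that("with one atlas the pipeline equals the single-atlas MAP", {
  ph <- small_phantom(dims = 24, noise_sd = 3, seed = 61)
  pop <- generate_population(ph, population_spec(n_atlases = 1, amplitude = 1.5,
                                                 smoothness = 5, seed = 62))
  fit <- likelihood_fusion(ph$image, pop, fast_reg_config(max_iter = 2),
                           fusion_config(), kernel_params())
  expect_lte(nrow(fit$trace), 2)            # noise-free-ish self consistency
  # independent MAP: warp priors, score every candidate label, argmax with
  # the documented tie-breaks
  reg <- fit$registrations[[1]]
  atlas <- pop[[1]]
  box <- compute_roi(warp_labels(atlas$labels, reg$phi, "nearest"), 4)
  pr <- warp_labels(atlas$full_labels, reg$phi, "prob")
  st <- estimate_chart_stats(atlas$image, atlas$full_labels)
  ids <- setdiff(sort(unique(as.vector(atlas$full_labels$labels))), 0L)
  idx <- likefuse:::roi_indices(box)
  iv <- as.vector(ph$image$values[idx$i, idx$j, idx$k])
  nroi <- length(iv)
  S <- matrix(NA_real_, nroi, length(ids))
  P <- matrix(NA_real_, nroi, length(ids))
  for (j in seq_along(ids)) {
    mu <- st$mean[st$label == ids[j]]; s2 <- st$var[st$label == ids[j]]
    pj <- as.vector(pr$probs[, , , which(pr$label_ids == ids[j])][
      idx$i, idx$j, idx$k])
    P[, j] <- pj
    S[, j] <- -0.5 * log(2 * pi * s2) - (iv - mu)^2 / (2 * s2) +
      pmax(log(pj), -30)
  }
  map_lab <- integer(nroi)
  for (x in seq_len(nroi)) {
    best <- which(S[x, ] == max(S[x, ]))
    if (length(best) > 1) best <- best[which.max(P[x, best])]
    map_lab[x] <- ids[best[1]]
  }
  got <- as.vector(fit$segmentation$labels[idx$i, idx$j, idx$k])
  expect_identical(got, map_lab)
})

test_that("atlas order does not change the fused segmentation", {
  ph <- small_phantom(dims = 24, noise_sd = 3, seed = 71)
  pop <- generate_population(ph, population_spec(n_atlases = 3, amplitude = 1.5,
                                                 smoothness = 5, seed = 72))
  fit <- likelihood_fusion(ph$image, pop, fast_reg_config(max_iter = 2),
                           fusion_config(), kernel_params())
  perm <- c(3, 1, 2)
  fit2 <- likelihood_fusion(ph$image, pop[perm], fast_reg_config(max_iter = 2),
                            fusion_config(), kernel_params(),
                            registrations = fit$registrations[perm])
  expect_identical(fit2$segmentation$labels, fit$segmentation$labels)
  # every ROI voxel carries a structure or tissue label
  idx <- likefuse:::roi_indices(fit$roi)
  expect_true(all(fit$segmentation$labels[idx$i, idx$j, idx$k] > 0))
})
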