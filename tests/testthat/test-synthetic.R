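# Phantom and atlas-population generators.

test_that("noise-free phantom has exactly the stated intensity levels", {
  sp <- phantom_spec(dims = c(24, 24, 24), noise_sd = 0,
                     structures = list(list(name = "s", center = c(11, 11, 11),
                                            radii = c(4, 4, 4), mean = 100)))
  ph <- generate_phantom(sp)
  vals <- sort(unique(as.vector(ph$image$values)))
  # one structure level + three tissue levels
  expect_setequal(vals, sort(unique(c(100, sp$tissue_means))))
  inside <- ph$labels$labels == 1L
  expect_true(all(ph$image$values[inside] == 100))
})

test_that("generators are pure functions of (spec, seed)", {
  sp <- phantom_spec(dims = c(20, 20, 20), seed = 42)
  a <- generate_phantom(sp); b <- generate_phantom(sp)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$full_labels$labels, b$full_labels$labels)
  ph <- generate_phantom(phantom_spec(dims = c(24, 24, 24), seed = 3))
  ps <- population_spec(n_atlases = 3, amplitude = 1.5, smoothness = 5, seed = 9)
  p1 <- generate_population(ph, ps); p2 <- generate_population(ph, ps)
  for (i in 1:3) {
    expect_identical(p1[[i]]$image$values, p2[[i]]$image$values)
    expect_identical(p1[[i]]$labels$labels, p2[[i]]$labels$labels)
  }
  # generator must not disturb the caller's RNG stream
  set.seed(7); x1 <- runif(1)
  set.seed(7); invisible(generate_phantom(sp)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("ellipsoid rasterization matches the brute-force membership scan", {
  sp <- phantom_spec(dims = c(32, 32, 32), noise_sd = 0,
                     structures = list(list(name = "s",
                                            center = c(15.5, 15.5, 15.5),
                                            radii = c(4, 4, 4), mean = 100)))
  ph <- generate_phantom(sp)
  cnt <- 0L
  for (x in 0:31) for (y in 0:31) for (z in 0:31) {
    if (sum(((c(x, y, z) - 15.5) / 4)^2) <= 1) cnt <- cnt + 1L
  }
  expect_identical(sum(ph$labels$labels == 1L), cnt)
  expect_error(generate_phantom(phantom_spec(
    dims = c(16, 16, 16),
    structures = list(list(name = "out", center = c(14, 8, 8),
                           radii = c(4, 2, 2), mean = 50)))), "fit within")
})

test_that("random diffeomorphisms are invertible with positive Jacobian", {
  d <- c(32, 32, 32)
  # amplitude 0 is the identity
  id <- random_diffeomorphism(d, 0, 6, seed = 1)
  expect_equal(max(abs(id$forward - likefuse:::identity_map(d))), 0)
  phi <- random_diffeomorphism(d, 2, 6, seed = 5)
  expect_gt(likefuse:::min_interior_jacobian(phi$forward), 0)
  # fixed-point inversion oracle: iterate psi(x) <- x - disp(psi(x)) on the
  # forward displacement, then compare with the stored inverse composition
  disp <- phi$forward - likefuse:::identity_map(d)
  psi <- likefuse:::identity_map(d)
  idm <- likefuse:::identity_map(d)
  for (it in 1:40) {
    v <- likefuse:::interp_field(disp, as.vector(psi[, , , 1]),
                                 as.vector(psi[, , , 2]),
                                 as.vector(psi[, , , 3]))
    for (c in 1:3) psi[, , , c] <- idm[, , , c] - array(v[, c], d)
  }
  comp <- likefuse:::compose_maps(phi$forward, psi)
  err <- sqrt(rowSums(matrix(comp - idm, ncol = 3)^2))
  interior <- rowSums(matrix(abs(idm - 15.5), ncol = 3) > 11.5) == 0
  expect_lt(max(err[interior]), 0.25)
  # and phi o phi^{-1} itself stays within tolerance
  expect_lt(likefuse:::inverse_consistency_error(phi), 0.25)
})

test_that("population atlases converge to the phantom as amplitude, jitter -> 0", {
  ph <- generate_phantom(phantom_spec(dims = c(24, 24, 24), seed = 2))
  pop0 <- generate_population(ph, population_spec(n_atlases = 1, amplitude = 0,
                                                  jitter_sd = 0, seed = 4))
  expect_equal(pop0[[1]]$image$values, ph$image$values, tolerance = 1e-12)
  expect_identical(pop0[[1]]$labels$labels, ph$labels$labels)
  # labels are conserved under nearest-neighbour warping
  pop <- generate_population(ph, population_spec(n_atlases = 2, amplitude = 2,
                                                 smoothness = 5, seed = 4))
  for (a in pop) {
    expect_true(all(unique(as.vector(a$labels$labels)) %in%
                      c(0L, as.integer(names(ph$labels$dictionary)))))
    expect_identical(a$full_labels$dictionary, ph$full_labels$dictionary)
  }
})

test_that("corrupt_atlas modes behave as documented", {
  ph <- generate_phantom(phantom_spec(dims = c(32, 32, 32), seed = 6))
  atlas <- generate_population(ph, population_spec(n_atlases = 1, seed = 8))[[1]]
  shifted <- corrupt_atlas(atlas, "shift_labels", shift = 6)
  # direct Dice computation: a 6-voxel shift on ~4-voxel-radius structures
  # destroys overlap
  dd <- vapply(1:5, function(k) dice(shifted$labels, atlas$labels, k),
               numeric(1))
  expect_true(all(dd < 0.5))
  expect_identical(shifted$image$values, atlas$image$values)
  inv <- corrupt_atlas(atlas, "invert_contrast")
  expect_identical(inv$labels$labels, atlas$labels$labels)
  expect_equal(cor(as.vector(inv$image$values), as.vector(atlas$image$values)),
               -1, tolerance = 1e-12)
  expect_error(corrupt_atlas(atlas, "upside_down"), "unknown mode")
})
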