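# Dice overlap and the randomization test.

random_label_pair <- function(d = c(6, 6, 6), K = 2) {
  g <- voxel_grid(d)
  dict <- stats::setNames(paste0("s", 1:K), 1:K)
  mk <- function() label_volume(array(sample(0:K, prod(d), replace = TRUE), d),
                                g, dict)
  list(auto = mk(), gold = mk())
}

test_that("dice agrees with brute-force set counting on random pairs", {
  set.seed(12)
  for (rep in 1:100) {
    pair <- random_label_pair()
    k <- sample(1:2, 1)
    a <- pair$auto$labels == k; g <- pair$gold$labels == k
    tp <- 0L; fp <- 0L; fn <- 0L
    for (x in seq_along(a)) {            # exhaustive voxel scan
      if (a[x] && g[x]) tp <- tp + 1L
      else if (a[x]) fp <- fp + 1L
      else if (g[x]) fn <- fn + 1L
    }
    expected <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
    expect_equal(dice(pair$auto, pair$gold, k), expected)
    # symmetry
    expect_equal(dice(pair$gold, pair$auto, k), expected)
  }
})

test_that("dice handles the stated special cases", {
  g <- voxel_grid(c(4, 4, 4))
  dict <- c("1" = "s")
  a <- array(0L, c(4, 4, 4)); a[1:2, 1, 1] <- 1L
  same <- label_volume(a, g, dict)
  expect_equal(dice(same, same, 1), 1)
  b <- array(0L, c(4, 4, 4)); b[3:4, 4, 4] <- 1L
  expect_equal(dice(same, label_volume(b, g, dict), 1), 0)
  empty <- label_volume(array(0L, c(4, 4, 4)), g, dict)
  expect_equal(dice(empty, empty, 1), 1)   # both-empty convention
  expect_error(dice(same, label_volume(array(0L, c(5, 5, 5)),
                                       voxel_grid(c(5, 5, 5)), dict), 1),
               "different grids")
})

test_that("dice_table rows are consistent and conserve volumes", {
  ph <- small_phantom(dims = 24, seed = 81)
  noisy <- ph$labels
  set.seed(82)
  flip <- sample(length(noisy$labels), 200)
  lab2 <- noisy$labels
  lab2[flip] <- sample(0:5, 200, replace = TRUE)
  auto <- label_volume(lab2, ph$labels$grid, ph$labels$dictionary)
  dt <- dice_table(auto, ph$labels, 1:5)
  expect_identical(nrow(dt), 5L)
  for (r in seq_len(nrow(dt))) {
    expect_identical(dt$TP[r] + dt$FN[r], dt$gold_vol[r])
    expect_identical(dt$TP[r] + dt$FP[r], dt$auto_vol[r])
    expect_equal(dt$dice[r], dice(auto, ph$labels, dt$label[r]))
  }
  # TP=3, FP=1, FN=2 evaluates to 6/9
  g <- voxel_grid(c(4, 4, 4)); dict <- c("1" = "s")
  a <- array(0L, c(4, 4, 4)); a[1:4, 1, 1] <- 1L          # auto: 4 voxels
  b <- array(0L, c(4, 4, 4)); b[1:3, 1, 1] <- 1L; b[1:2, 2, 1] <- 1L  # gold: 5
  row <- dice_table(label_volume(a, g, dict), label_volume(b, g, dict), 1L)
  expect_identical(c(row$TP, row$FP, row$FN), c(3L, 1L, 2L))
  expect_equal(row$dice, 2 * 3 / (2 * 3 + 1 + 2), tolerance = 1e-12)
  expect_equal(round(row$dice, 4), 0.6667)
})

test_that("randomization test matches exact enumeration for n = 3 + 3", {
  a <- c(1.2, 2.1, 0.7); b <- c(2.5, 3.1, 2.2)
  res <- permutation_test(a, b, exact = TRUE)
  # independent enumeration oracle over all choose(6,3) = 20 splits
  pool <- c(a, b)
  tstat <- function(x, y) {
    (mean(x) - mean(y)) / sqrt(var(x) / 3 + var(y) / 3)
  }
  t_obs <- tstat(a, b)
  splits <- combn(6, 3)
  tt <- apply(splits, 2, function(ix) tstat(pool[ix], pool[-ix]))
  expect_identical(res$n_perm, 20L)
  expect_equal(res$p, mean(abs(tt) >= abs(t_obs) - 1e-12))
})

test_that("randomization test: reproducibility, null and separated cases", {
  set.seed(31)
  a <- rnorm(8); b <- rnorm(8)
  p1 <- permutation_test(a, b, n_perm = 500, seed = 7)$p
  p2 <- permutation_test(a, b, n_perm = 500, seed = 7)$p
  expect_identical(p1, p2)
  # identical groups: t = 0 is never beaten, p well above 0.5
  p_same <- permutation_test(a, a, n_perm = 200, seed = 1)$p
  expect_gt(p_same, 0.5)
  # a 10-sd shift is detected at the add-one floor
  b10 <- a + 10 * sd(a)
  p_shift <- permutation_test(a, b10, n_perm = 10000, seed = 3)$p
  expect_lte(p_shift, 0.01)
  expect_error(permutation_test(c(1, 1), c(1, 1), 10), "zero variance")
})

test_that("single-vs-multi harness reports equal scores for identical atlases", {
  ph <- small_phantom(dims = 24, noise_sd = 2, seed = 91)
  one <- generate_population(ph, population_spec(n_atlases = 1, amplitude = 0,
                                                 jitter_sd = 0, seed = 92))[[1]]
  atlases <- list(one, one)
  rep1 <- compare_single_vs_multi(
    list(list(image = ph$image, gold = ph$labels)), atlases,
    reg_config = fast_reg_config(max_iter = 2), n_perm = 50)
  d <- rep1$dice
  # one fusion row set plus one per atlas, per structure
  expect_identical(sum(d$method == "fusion"), 5L)
  expect_identical(sum(d$method == "single"), 10L)
  for (k in 1:5) {
    f <- d$dice[d$method == "fusion" & d$label == k]
    s <- d$dice[d$method == "single" & d$label == k]
    expect_equal(s, rep(f, 2))
  }
})
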