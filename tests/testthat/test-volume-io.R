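# Volume containers, ROI arithmetic and NIfTI-1 round trips.

test_that("NIfTI round trip preserves values, spacing and affine", {
  d <- c(8L, 8L, 8L)
  aff <- diag(c(0.9375, 0.9375, 1.2, 1))
  aff[1:3, 4] <- c(-10, 5, 2.5)
  g <- voxel_grid(d, c(0.9375, 0.9375, 1.2), aff)
  vol <- intensity_volume(array(0, d), g)
  tf <- tempfile(fileext = ".nii.gz")
  write_volume(vol, tf)
  back <- read_volume(tf)
  expect_identical(back$values, vol$values)
  expect_equal(back$grid$spacing, c(0.9375, 0.9375, 1.2), tolerance = 1e-6)
  expect_lt(max(abs(back$grid$affine - aff)), 1e-5)

  # float32 data round-trips bit-for-bit once quantized to float32
  v2 <- intensity_volume(array(seq_len(prod(d)) / 7, d), g)
  write_volume(v2, tf)
  again <- read_volume(tf)
  write_volume(again, tf)
  expect_identical(read_volume(tf)$values, again$values)
  unlink(tf)
})

test_that("label volumes round trip with dictionary checks", {
  g <- voxel_grid(c(6, 6, 6))
  lab <- array(0L, c(6, 6, 6)); lab[2:3, 2:3, 2:3] <- 1L; lab[5, 5, 5] <- 2L
  dict <- c("1" = "hippocampus", "2" = "ventricle")
  lv <- label_volume(lab, g, dict)
  tf <- tempfile(fileext = ".nii")
  write_volume(lv, tf)
  back <- read_labels(tf, dict)
  expect_identical(back$labels, lv$labels)
  # unknown label id in file is an error
  expect_error(read_labels(tf, c("1" = "hippocampus")), "absent")
  # all-zero labels are a valid empty segmentation
  write_volume(label_volume(array(0L, c(6, 6, 6)), g, dict), tf)
  expect_s3_class(read_labels(tf, dict), "label_volume")
  unlink(tf)
})

test_that("malformed inputs are rejected", {
  expect_error(read_volume(tempfile()), "not found")
  expect_error(label_volume(array(-1L, c(2, 2, 2)), voxel_grid(c(2, 2, 2))),
               "non-negative")
  expect_error(voxel_grid(c(4, 4, 4), affine = matrix(0, 4, 4)), "singular")
  # a 2-D NIfTI (ndim = 2) must be refused
  tf <- tempfile(fileext = ".nii")
  write_volume(intensity_volume(array(0, c(4, 4, 1)), voxel_grid(c(4, 4, 1))), tf)
  raw <- readBin(tf, "raw", file.info(tf)$size)
  con <- file(tf, "wb"); writeBin(raw[1:40], con)
  writeBin(as.integer(c(2, 4, 4, 1, 1, 1, 1, 1)), con, size = 2,
           endian = "little")
  writeBin(raw[57:length(raw)], con); close(con)
  expect_error(read_volume(tf), "3-D")
  unlink(tf)
})

test_that("our NIfTI writer agrees with nibabel", {
  # independent oracle: read the file with nibabel through python
  py <- Sys.which("python")
  d <- c(5L, 6L, 7L)
  aff <- diag(c(0.9375, 0.9375, 1.2, 1)); aff[1:3, 4] <- c(1, -2, 3)
  vol <- intensity_volume(array(rnorm(prod(d)), d),
                          voxel_grid(d, c(0.9375, 0.9375, 1.2), aff))
  tf <- tempfile(fileext = ".nii.gz")
  write_volume(vol, tf)
  out <- system2(py, c("-c", shQuote(paste0(
    "import nibabel, numpy; img = nibabel.load('", tf, "'); ",
    "d = img.get_fdata(); ",
    "print(d.shape, round(float(d.sum()), 4), ",
    "numpy.round(img.affine, 4).tolist())"))), stdout = TRUE)
  expect_match(out, "\\(5, 6, 7\\)")
  expect_match(out, as.character(round(sum(vol$values), 4)), fixed = TRUE)
  expect_match(out, "0.9375", fixed = TRUE)
  unlink(tf)
})

test_that("compute_roi matches a brute-force scan and is order-invariant", {
  g <- voxel_grid(c(10, 10, 10))
  mk <- function(from, to) {
    a <- array(0L, c(10, 10, 10))
    a[(from[1] + 1):(to[1] + 1), (from[2] + 1):(to[2] + 1),
      (from[3] + 1):(to[3] + 1)] <- 1L
    label_volume(a, g, c("1" = "s"))
  }
  # one structure occupying voxels [3..5]^3, margin 1
  box <- compute_roi(mk(c(3, 3, 3), c(5, 5, 5)), margin_vox = 1)
  expect_identical(box$lower, c(2L, 2L, 2L))
  expect_identical(box$upper, c(7L, 7L, 7L))
  # margin 0, two structures -> union bounding box
  b2 <- compute_roi(list(mk(c(1, 2, 3), c(2, 3, 4)), mk(c(6, 0, 5), c(8, 1, 6))),
                    margin_vox = 0)
  expect_identical(b2$lower, c(1L, 0L, 3L))
  expect_identical(b2$upper, c(9L, 4L, 7L))
  # structure at the grid edge, margin 2, vs brute-force over nonzero indices
  lv <- mk(c(8, 0, 4), c(9, 2, 9))
  b3 <- compute_roi(list(lv), margin_vox = 2)
  nz <- which(lv$labels != 0, arr.ind = TRUE) - 1L
  expect_identical(b3$lower, pmax(0L, apply(nz, 2, min) - 2L))
  expect_identical(b3$upper, pmin(10L, apply(nz, 2, max) + 3L))
  # order invariance
  vols <- list(mk(c(1, 1, 1), c(3, 3, 3)), mk(c(5, 6, 2), c(7, 8, 4)),
               mk(c(0, 4, 8), c(1, 5, 9)))
  b_fwd <- compute_roi(vols, 1)
  b_rev <- compute_roi(rev(vols), 1)
  expect_identical(b_fwd, b_rev)
  expect_error(compute_roi(label_volume(array(0L, c(10, 10, 10)), g)),
               "no nonzero")
})

test_that("crop/uncrop preserve values and world coordinates", {
  g <- voxel_grid(c(9, 9, 9), c(0.9375, 0.9375, 1.2))
  vol <- intensity_volume(array(seq_len(729), c(9, 9, 9)), g)
  box <- roi_box(c(2, 3, 1), c(6, 8, 5))
  cr <- crop(vol, box)
  expect_identical(dim(cr$values), c(4L, 5L, 4L))
  # world coordinate of the box corner equals voxel (0,0,0) after crop
  expect_equal(as.vector(cr$grid$affine %*% c(0, 0, 0, 1)),
               as.vector(g$affine %*% c(box$lower, 1)))
  uc <- uncrop(cr, box, g, fill = 0)
  masked <- array(0, c(9, 9, 9))
  masked[3:6, 4:8, 2:5] <- vol$values[3:6, 4:8, 2:5]
  expect_identical(uc$values, masked)
  # 1-voxel box
  one <- crop(vol, roi_box(c(4, 4, 4), c(5, 5, 5)))
  expect_identical(dim(one$values), c(1L, 1L, 1L))
  expect_identical(one$values[1, 1, 1], vol$values[5, 5, 5])
  expect_error(crop(vol, roi_box(c(2, 2, 2), c(12, 5, 5))), "exceeds")
})

test_that("resampling onto a shifted grid relocates content", {
  g <- voxel_grid(c(8, 8, 8))
  vals <- array(0, c(8, 8, 8)); vals[4, 4, 4] <- 1
  vol <- intensity_volume(vals, g)
  aff2 <- diag(4); aff2[1:3, 4] <- c(1, 0, 0)   # shifted one voxel in world x
  g2 <- voxel_grid(c(8, 8, 8), affine = aff2)
  rs <- resample_to(vol, g2, "linear")
  expect_equal(rs$values[3, 4, 4], 1)
  lab <- label_volume((vals > 0) * 2L, g, c("2" = "s"))
  rl <- resample_to(lab, g2)
  expect_identical(rl$labels[3, 4, 4], 2L)
  expect_identical(sort(unique(as.vector(rl$labels))), c(0L, 2L))
})
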