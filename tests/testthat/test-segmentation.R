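toy_slice <- function(vals, nr = NULL) {
  m <- if (is.matrix(vals)) vals else matrix(vals, nrow = nr)
  slice2d(m, pixel_spacing = c(1, 1))
}

test_that("the 4x4 toy case picks the documented threshold and ROI", {
  m <- matrix(5, 4, 4)
  m[1, 1] <- 10            # contralateral maximum
  m[3, 3] <- 11; m[3, 4] <- 12; m[4, 4] <- 15   # tumor pixels
  sl <- toy_slice(m)
  brain <- roi_mask(matrix(TRUE, 4, 4), sl)
  contra <- roi_mask(matrix(c(rep(TRUE, 8), rep(FALSE, 8)), 4, 4), sl)
  res <- threshold_segment(sl, brain, contra)
  expect_equal(res$threshold, 11)
  expect_equal(res$contralateral_max, 10)
  expect_equal(res$n_roi_voxels, 3L)
  expect_true(all(which(res$roi$mask) == which(m >= 11)))
})

test_that("a contralateral global maximum forces an empty ROI", {
  m <- matrix(runif(16, 0, 5), 4, 4)
  m[2, 1] <- 99
  sl <- toy_slice(m)
  brain <- roi_mask(matrix(TRUE, 4, 4), sl)
  contra <- roi_mask(matrix(c(rep(TRUE, 8), rep(FALSE, 8)), 4, 4), sl)
  res <- threshold_segment(sl, brain, contra)
  expect_equal(res$n_roi_voxels, 0L)
})

test_that("threshold equals the exhaustive search on random toy slices", {
  set.seed(11)
  for (i in 1:100) {
    m <- matrix(sample(0:20, 36, replace = TRUE), 6, 6)
    sl <- toy_slice(m)
    brain_arr <- matrix(runif(36) < 0.9, 6, 6)
    contra_arr <- brain_arr & matrix(rep(c(TRUE, FALSE), each = 18), 6, 6)
    if (!any(contra_arr)) contra_arr[1, 1] <- brain_arr[1, 1] <- TRUE
    brain <- roi_mask(brain_arr, sl)
    contra <- roi_mask(contra_arr, sl)
    res <- threshold_segment(sl, brain, contra)
    orc <- oracle_threshold(m, brain_arr, contra_arr)
    if (is.finite(orc$threshold)) {
      expect_equal(res$threshold, orc$threshold)
      expect_identical(res$roi$mask, orc$roi)
    } else {
      expect_equal(res$n_roi_voxels, 0L)
    }
    expect_equal(sum(res$roi$mask & contra_arr), 0L)  # invariant
  }
})

test_that("raising a contralateral pixel can only shrink the ROI", {
  set.seed(12)
  m <- matrix(sample(0:30, 64, replace = TRUE), 8, 8)
  sl <- toy_slice(m)
  brain <- roi_mask(matrix(TRUE, 8, 8), sl)
  contra_arr <- matrix(rep(c(TRUE, FALSE), each = 32), 8, 8)
  contra <- roi_mask(contra_arr, sl)
  base <- threshold_segment(sl, brain, contra)
  for (i in 1:20) {
    m2 <- m
    pick <- sample(which(contra_arr), 1)
    m2[pick] <- m2[pick] + sample(1:10, 1)
    res2 <- threshold_segment(toy_slice(m2), brain, contra)
    # ROI can lose pixels but never gain any (the raised pixel itself
    # is contralateral, hence never in either ROI)
    expect_true(all(which(res2$roi$mask) %in% which(base$roi$mask)))
  }
})

test_that("noise-free tumor strictly above contralateral is fully recovered", {
  m <- matrix(1, 10, 10)
  tumor <- matrix(FALSE, 10, 10); tumor[6:8, 6:8] <- TRUE
  m[tumor] <- 7
  sl <- toy_slice(m)
  brain <- roi_mask(matrix(TRUE, 10, 10), sl)
  contra <- roi_mask(matrix(rep(c(TRUE, FALSE), each = 50), 10, 10), sl)
  res <- threshold_segment(sl, brain, contra)
  expect_identical(res$roi$mask, tumor)
})

test_that("largest-component postfilter drops satellite noise pixels", {
  m <- matrix(0, 10, 10)
  m[2:4, 2:4] <- 5          # main blob (9 px)
  m[9, 9] <- 6              # satellite
  sl <- toy_slice(m)
  brain <- roi_mask(matrix(TRUE, 10, 10), sl)
  contra <- roi_mask(matrix(c(rep(FALSE, 50), rep(TRUE, 50)), 10, 10) &
                       m == 0, sl)
  res <- threshold_segment(sl, brain, contra, largest_component = TRUE)
  expect_equal(res$n_roi_voxels, 9L)
  expect_false(res$roi$mask[9, 9])
})

test_that("segmentation rejects invalid masks", {
  sl <- toy_slice(matrix(1, 4, 4))
  brain <- roi_mask(matrix(TRUE, 4, 4), sl)
  empty <- roi_mask(matrix(FALSE, 4, 4), sl)
  expect_error(threshold_segment(sl, empty, empty), "empty")
  expect_error(threshold_segment(sl, brain, empty), "empty")
  outside <- roi_mask(matrix(c(TRUE, rep(FALSE, 15)), 4, 4), sl)
  brain2 <- roi_mask(matrix(c(FALSE, rep(TRUE, 15)), 4, 4), sl)
  expect_error(threshold_segment(sl, brain2, outside), "contained")
})

test_that("manual ROI loading validates shape and binarity", {
  d <- withr::local_tempdir()
  grid <- image3d(array(0, c(6, 6, 4)), spacing = c(0.25, 0.25, 0.5))
  good <- array(0, c(6, 6, 4)); good[2:3, 2:3, 2] <- 1
  write_volume(image3d(good, grid$spacing), file.path(d, "roi.nii.gz"))
  m <- manual_roi_load(file.path(d, "roi.nii.gz"), grid)
  expect_s3_class(m, "roi_mask")
  expect_equal(sum(m$mask), 4)

  write_volume(image3d(good * 2.5, grid$spacing), file.path(d, "bad.nii.gz"))
  expect_error(manual_roi_load(file.path(d, "bad.nii.gz"), grid), "binary")
  write_volume(image3d(array(0, c(3, 3, 3)), grid$spacing),
               file.path(d, "shape.nii.gz"))
  expect_error(manual_roi_load(file.path(d, "shape.nii.gz"), grid), "shape")
  write_volume(image3d(array(0, c(6, 6, 4)), grid$spacing),
               file.path(d, "zero.nii.gz"))
  expect_warning(manual_roi_load(file.path(d, "zero.nii.gz"), grid), "empty")
})

test_that("maximum intensity projection equals the elementwise oracle", {
  s1 <- toy_slice(matrix(1:12, 3, 4))
  expect_equal(max_intensity_projection(list(s1))$pixels, s1$pixels)
  zero <- toy_slice(matrix(0, 3, 4))
  expect_equal(max_intensity_projection(list(s1, zero))$pixels, s1$pixels)
  set.seed(13)
  stack <- lapply(1:3, function(i) toy_slice(matrix(rnorm(12), 3, 4)))
  mip <- max_intensity_projection(stack)
  brute <- stack[[1]]$pixels
  for (i in 2:3) for (r in 1:3) for (c in 1:4)
    brute[r, c] <- max(brute[r, c], stack[[i]]$pixels[r, c])
  expect_equal(mip$pixels, brute)
  expect_error(max_intensity_projection(list()), "empty")
  expect_error(max_intensity_projection(list(s1, toy_slice(matrix(0, 2, 2)))),
               "congruent")
})

test_that("mirrored contralateral mask stays on the tumor-free side", {
  sl <- slice2d(matrix(0, 20, 20), pixel_spacing = c(0.5, 0.5),
                origin = c(-5, -5))
  brain <- roi_mask(matrix(TRUE, 20, 20), sl)
  contra <- mirror_contralateral(brain, midline = 0, tumor_side = 1,
                                 guard = 0.5)
  idx <- which(contra$mask, arr.ind = TRUE)
  xs <- -5 + (idx[, 1] - 1) * 0.5
  expect_true(all(xs < -0.5))
  expect_gt(sum(contra$mask), 0)
})
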