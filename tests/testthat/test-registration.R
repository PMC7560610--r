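make_pair <- function(va, vb, dim = NULL) {
  if (is.null(dim)) dim <- c(length(va), 1, 1)
  a <- image3d(array(va, dim), spacing = c(1, 1, 1))
  b <- image3d(array(vb, dim), spacing = c(1, 1, 1))
  list(a = a, b = b, mask = roi_mask(array(TRUE, dim), a))
}

test_that("joint histogram counts masked voxels into the right cells", {
  p <- make_pair(rep(5, 8), rep(5, 8), dim = c(2, 2, 2))
  h <- joint_histogram(p$a, p$b, p$mask, bins = 16)
  expect_equal(sum(h), 8)
  expect_equal(sum(h > 0), 1L)  # constant pair: one occupied cell

  # 4-voxel toy pair, hand-binned: bins = 2 over [min, max] of each
  # image. a = (0, 0, 10, 10) -> bins (1, 1, 2, 2); b = (0, 7, 0, 10)
  # with clipping percentiles (0, 1) -> edges [0, 10], so bins
  # (1, 2, 1, 2). Hand-counted table: (1,1)=1, (1,2)=1, (2,1)=1, (2,2)=1.
  p4 <- make_pair(c(0, 0, 10, 10), c(0, 7, 0, 10), dim = c(4, 1, 1))
  h4 <- joint_histogram(p4$a, p4$b, p4$mask, bins = 2, clip = c(0, 1))
  expect_equal(h4, matrix(1, 2, 2))

  set.seed(1)
  pu <- make_pair(runif(8000), runif(8000), dim = c(20, 20, 20))
  hu <- joint_histogram(pu$a, pu$b, pu$mask, bins = 8, clip = c(0, 1))
  expect_lt(max(abs(hu / sum(hu) - 1 / 64)), 0.01)  # independent => flat

  expect_error(joint_histogram(p$a, p$b,
                               roi_mask(array(FALSE, c(2, 2, 2)), p$a), 16),
               "empty")
})

test_that("mutual information matches its analytic values", {
  expect_equal(mutual_information(matrix(c(50, 0, 0, 50), 2, 2)), log(2),
               tolerance = 1e-12)
  outer_h <- outer(c(10, 30, 60), c(20, 25, 55))
  expect_lt(abs(mutual_information(outer_h)), 1e-12)
  # MI(X, X) equals the marginal entropy
  diag_h <- diag(c(5, 15, 30, 50))
  px <- c(5, 15, 30, 50) / 100
  expect_equal(mutual_information(diag_h), -sum(px * log(px)),
               tolerance = 1e-12)
  expect_error(mutual_information(matrix(0, 2, 2)), "positive")
})

test_that("MI is symmetric, nonnegative and bin-permutation invariant", {
  set.seed(2)
  for (i in 1:20) {
    h <- matrix(rpois(64, 3), 8, 8)
    if (sum(h) == 0) h[1, 1] <- 1
    mi <- mutual_information(h)
    expect_gte(mi, -1e-14)
    expect_equal(mi, mutual_information(t(h)), tolerance = 1e-12)
    perm <- sample(8)
    expect_equal(mi, mutual_information(h[perm, perm]), tolerance = 1e-12)
  }
})

test_that("self-registration returns the initial transform exactly", {
  img <- smooth_random_image(dim = c(20, 20, 14), seed = 6)
  mask <- roi_mask(array(TRUE, dim(img$voxels)), img)
  expect_warning(
    tr <- register(img, img, mask,
                   registration_settings(levels = 1L, presearch_mm = 1,
                                         n_restarts = 1L, rng_seed = 3)),
    "did not improve")
  expect_equal(tr$matrix, diag(4))
  expect_false(attr(tr, "improved"))
})

test_that("a known translation of a smooth image is recovered within 0.1 mm", {
  img <- blob_image(dim = c(26, 26, 18), seed = 8)
  truth <- translation_transform(c(1.0, -0.5, 0.25))
  moved <- resample(img, truth, img, interp = "linear")
  interior <- array(FALSE, dim(img$voxels))
  interior[5:22, 5:22, 4:15] <- TRUE
  mask <- roi_mask(interior, img)
  tr <- register(moved, img, mask,
                 registration_settings(rng_seed = 5, presearch_mm = 1.5))
  # `moved` holds img pulled back through `truth`, so the recovered
  # moving-to-fixed transform is `truth` itself
  expect_lt(max(abs(tr$matrix[1:3, 4] - c(1.0, -0.5, 0.25))), 0.1)
})

test_that("registration is invariant to intensity rescaling (MI property)", {
  img <- blob_image(dim = c(22, 22, 16), seed = 12, n = 10)
  truth <- translation_transform(c(0.6, -0.4, 0))
  moved <- resample(img, truth, img, interp = "linear")
  moved2 <- moved
  moved2$voxels <- 3 * moved2$voxels + 10  # affine intensity remap
  interior <- array(FALSE, dim(img$voxels))
  interior[5:18, 5:18, 4:13] <- TRUE
  mask <- roi_mask(interior, img)
  s <- registration_settings(rng_seed = 5, presearch_mm = 1)
  t1 <- register(moved, img, mask, s)
  t2 <- register(moved2, img, mask, s)
  expect_lt(max(abs(t1$matrix[1:3, 4] - t2$matrix[1:3, 4])), 0.05)
})

test_that("slab-to-slice matching follows the slice-block arithmetic", {
  # 1-mm slabs against 0.5-mm MRI slices, aligned face: 2 slices per slab
  block <- slice_block_spec(n_slots = 5, pitch = 1, face0 = 0,
                            mri_spacing = 0.5, mri_origin = 0.25, mri_n = 10)
  tab <- match_slices(block)
  expect_true(all(lengths(tab$slices) == 2L))
  expect_equal(tab$slices[[1]], c(1L, 2L))
  expect_equal(tab$representative, c(1L, 3L, 5L, 7L, 9L))

  # pitch equal to the slice spacing: identity mapping
  b2 <- slice_block_spec(4, pitch = 0.5, face0 = 0, mri_spacing = 0.5,
                         mri_origin = 0.25, mri_n = 4)
  t2 <- match_slices(b2)
  expect_equal(t2$representative, 1:4)
  expect_equal(unlist(t2$slices), 1:4)

  # arbitrary offset: equals the brute-force centre-in-interval test
  set.seed(3)
  for (i in 1:10) {
    face0 <- runif(1, -2, 2)
    sp <- runif(1, 0.3, 0.7)
    org <- runif(1, -1, 1)
    b <- slice_block_spec(6, pitch = 1, face0 = face0, mri_spacing = sp,
                          mri_origin = org, mri_n = 20)
    tb <- suppressWarnings(match_slices(b))
    centers <- org + (0:19) * sp
    for (k in 1:6) {
      lo <- face0 + (k - 1); hi <- lo + 1
      expect_equal(tb$slices[[k]], which(centers >= lo & centers < hi))
    }
  }
  # slab fully outside the MRI extent warns and returns empty
  bout <- slice_block_spec(1, pitch = 1, face0 = 50, mri_spacing = 0.5,
                           mri_origin = 0, mri_n = 4)
  expect_warning(tout <- match_slices(bout), "outside")
  expect_length(tout$slices[[1]], 0L)
})

test_that("similarity fit recovers exact transforms and matches the oracle", {
  src <- random_landmarks_2d(6, seed = 21)
  # identity case
  f0 <- fit_similarity_2d(src, src)
  expect_equal(f0$s, 1, tolerance = 1e-12)
  expect_equal(f0$theta, 0, tolerance = 1e-12)
  expect_lt(max(abs(f0$translation)), 1e-12)
  expect_lt(max(f0$residuals), 1e-12)

  # generate-and-recover: theta = 30 deg, s = 1.1, t = (5, -3)
  truth <- similarity_transform_2d(1.1, theta = 30 * pi / 180,
                                   shift = c(5, -3))
  dst <- apply_transform(truth, src)
  f <- fit_similarity_2d(src, dst)
  expect_equal(f$s, 1.1, tolerance = 1e-9)
  expect_equal(f$theta, 30 * pi / 180, tolerance = 1e-9)
  expect_equal(f$translation, c(5, -3), tolerance = 1e-9)
  expect_lt(f$rms, 1e-9)

  # with noise the fit beats any perturbed transform in SSE
  set.seed(22)
  dstn <- dst
  noise <- matrix(rnorm(12, sd = 0.1), 6, 2)
  dstn$x <- dstn$x + noise[, 1]; dstn$y <- dstn$y + noise[, 2]
  fn <- fit_similarity_2d(src, dstn)
  sse <- function(tr) sum((apply_transform(tr, landmark_coords(src)) -
                             landmark_coords(dstn))^2)
  sse_fit <- sse(fn$transform)
  for (i in 1:200) {
    pert <- similarity_transform_2d(fn$s * exp(rnorm(1, 0, 0.02)),
                                    fn$theta + rnorm(1, 0, 0.02),
                                    fn$translation + rnorm(2, 0, 0.05))
    expect_gte(sse(pert), sse_fit - 1e-12)
  }
})

test_that("similarity fit enforces pairing and minimum configuration", {
  a <- landmark_set(c("p", "q"), rbind(c(0, 0), c(1, 1)))
  b <- landmark_set(c("p", "r"), rbind(c(0, 0), c(1, 1)))
  expect_error(fit_similarity_2d(a, b), "r")
  one <- landmark_set("p", rbind(c(0, 0)))
  expect_error(fit_similarity_2d(one, one), "2 landmark")
  coin <- landmark_set(c("p", "q"), rbind(c(1, 1), c(1, 1)))
  expect_error(fit_similarity_2d(coin, coin), "coincident")
  # collinear configurations are accepted
  col <- landmark_set(c("p", "q", "r"), cbind(0:2, 0:2))
  dst <- apply_transform(similarity_transform_2d(1.2, 0.3, c(1, 1)), col)
  fc <- fit_similarity_2d(col, dst)
  expect_equal(fc$s, 1.2, tolerance = 1e-9)
})

test_that("reflection handling: pre-flip only when allowed and better", {
  src <- random_landmarks_2d(6, seed = 30)
  flip <- landmark_coords(src); flip[, 1] <- -flip[, 1]
  dst <- landmark_set(src$label,
                      apply_transform(similarity_transform_2d(1.05, 0.2,
                                                              c(1, 2)), flip))
  f_no <- fit_similarity_2d(src, dst)
  f_yes <- fit_similarity_2d(src, dst, allow_reflection = TRUE)
  expect_true(f_yes$flipped)
  expect_lt(f_yes$rms, 1e-9)
  expect_gt(f_no$rms, f_yes$rms)
})

test_that("fluorescence slice registration resamples onto the MRI grid", {
  px <- matrix(0, 60, 60)
  px[20:40, 25:45] <- 1
  fl <- slice2d(px, pixel_spacing = c(0.1, 0.1), origin = c(0, 0))
  mri <- slice2d(matrix(0, 30, 30), pixel_spacing = c(0.2, 0.2),
                 origin = c(0, 0))
  lm_m <- random_landmarks_2d(6, seed = 31, space = "mri")
  lm_m$x <- abs(lm_m$x); lm_m$y <- abs(lm_m$y)
  # identity landmarks: the resampled slice equals plain grid resampling
  out <- register_fluorescence_slice(fl, mri, lm_m, lm_m)
  expect_equal(out$transform$matrix, diag(3))
  plain <- resample(fl, identity_transform(2), mri, interp = "linear")
  expect_equal(out$fluor_on_mri$pixels, plain$pixels)
  expect_equal(dim(out$mri_on_fluor$pixels), dim(fl$pixels))
})
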