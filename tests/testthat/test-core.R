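test_that("compose obeys the transform group laws", {
  T1 <- translation_transform(c(1, 0, 0))
  T2 <- translation_transform(c(0, 2, 0))
  expect_equal(compose(T1, T2)$matrix, translation_transform(c(1, 2, 0))$matrix)
  A <- random_similarity_3d(11)
  expect_equal(compose(A, identity_transform(3))$matrix, A$matrix)
  expect_equal(compose(identity_transform(3), A)$matrix, A$matrix)
  # associativity and inverse consistency on randomized similarities
  for (seed in 1:10) {
    B <- random_similarity_3d(seed)
    C <- random_similarity_3d(seed + 100)
    lhs <- compose(compose(A, B), C)$matrix
    rhs <- compose(A, compose(B, C))$matrix
    expect_lt(max(abs(lhs - rhs)), 1e-9)
    expect_lt(max(abs(compose(B, invert(B))$matrix - diag(4))), 1e-9)
    expect_lt(max(abs(invert(compose(B, C))$matrix -
                        compose(invert(C), invert(B))$matrix)), 1e-9)
  }
})

test_that("composition kind is the weakest of the operands", {
  r <- rigid_transform(c(0.1, 0, 0.2), shift = c(1, 2, 3))
  s <- scaling_transform(1.05, d = 3L)
  a <- scaling_transform(c(1, 1.1, 0.9))
  expect_identical(compose(r, r)$kind, "rigid")
  expect_identical(compose(r, s)$kind, "similarity")
  expect_identical(compose(s, a)$kind, "affine")
  expect_identical(invert(s)$kind, "similarity")
})

test_that("transform validation rejects mislabelled and singular matrices", {
  m <- diag(4); m[1, 1] <- 2
  expect_error(affine_transform(m, kind = "rigid"), "orthonormal")
  ms <- diag(4); ms[2, 2] <- 0
  expect_error(affine_transform(ms), "singular")
  m2 <- diag(4); m2[4, 1] <- 1
  expect_error(affine_transform(m2), "homogeneous")
  expect_error(compose(identity_transform(2), identity_transform(3)),
               "dimension")
})

test_that("invert is analytic on simple transforms and exact on random ones", {
  expect_equal(invert(identity_transform(3))$matrix, diag(4))
  expect_equal(invert(scaling_transform(2, d = 3L))$matrix,
               scaling_transform(0.5, d = 3L)$matrix)
  for (seed in 1:5) {
    t <- random_similarity_3d(seed)
    expect_lt(max(abs((invert(t)$matrix %*% t$matrix) - diag(4))), 1e-9)
  }
})

test_that("apply_transform maps points and landmark sets correctly", {
  ls <- landmark_set(c("a", "b"), rbind(c(1, 1, 1), c(0, 0, 0)), space = "s")
  out <- apply_transform(identity_transform(3), ls)
  expect_equal(landmark_coords(out), landmark_coords(ls))
  expect_identical(out$label, ls$label)
  expect_equal(as.numeric(apply_transform(translation_transform(c(0.3, 0, 0)),
                                          c(1, 1, 1))),
               c(1.3, 1, 1))
  rot90 <- rigid_transform(c(0, 0, pi / 2))
  expect_equal(as.numeric(apply_transform(rot90, c(1, 0, 0))),
               c(0, 1, 0), tolerance = 1e-12)
  expect_error(apply_transform(identity_transform(3), cbind(1, 2)),
               "2D.*3D|points are")
})

test_that("resample is exact where interpolation theory says it must be", {
  img <- smooth_random_image(seed = 3)
  same <- resample(img, identity_transform(3), img, interp = "linear")
  expect_equal(same$voxels, img$voxels)
  same_nn <- resample(img, identity_transform(3), img, interp = "nearest")
  expect_equal(same_nn$voxels, img$voxels)

  # a one-voxel translation with nearest interpolation is an index shift
  shift <- translation_transform(img$spacing * c(1, 0, 0))
  out <- resample(img, shift, img, interp = "nearest")
  d <- dim(img$voxels)
  expect_equal(out$voxels[1:(d[1] - 1), , ], img$voxels[2:d[1], , ])
  expect_true(all(out$voxels[d[1], , ] == 0))  # background fill

  # linear interpolation reproduces an affine ramp exactly on upsampling
  dim_c <- c(10, 10, 8)
  ax <- lapply(1:3, function(a) (seq_len(dim_c[a]) - 1) *
                 c(0.5, 0.5, 0.5)[a])
  g <- expand.grid(ax)
  ramp <- image3d(array(2 * g[[1]] - 3 * g[[2]] + 0.5 * g[[3]] + 1, dim_c),
                  spacing = c(0.5, 0.5, 0.5))
  fine <- image3d(array(0, c(17, 17, 13)), spacing = c(0.25, 0.25, 0.25))
  up <- resample(ramp, identity_transform(3), fine, interp = "linear")
  axf <- lapply(1:3, function(a) (seq_len(dim(fine$voxels)[a]) - 1) * 0.25)
  gf <- expand.grid(axf)
  expected <- array(2 * gf[[1]] - 3 * gf[[2]] + 0.5 * gf[[3]] + 1,
                    dim(fine$voxels))
  expect_lt(max(abs(up$voxels - expected)), 1e-6)
})

test_that("mask resampling stays binary and unknown interp is rejected", {
  img <- smooth_random_image(seed = 4)
  m <- roi_mask(img$voxels > 0, img)
  t <- rigid_transform(c(0, 0, 0.2), shift = c(0.3, -0.2, 0.1))
  out <- resample(m, t, img)
  expect_type(out$mask, "logical")
  expect_true(all(out$mask %in% c(TRUE, FALSE)))
  expect_error(resample(img, t, img, interp = "cubic"))
})

test_that("round-trip resampling recovers a band-limited image within 2%", {
  img <- smooth_random_image(dim = c(28, 28, 20), seed = 5, sigma_vox = 2.5)
  t <- rigid_transform(c(0.05, -0.04, 0.08), shift = c(0.6, -0.4, 0.3))
  fwd <- resample(img, t, img, interp = "linear")
  back <- resample(fwd, invert(t), img, interp = "linear")
  # judge only the interior: voxels that never touched the background fill
  rng <- diff(range(img$voxels))
  interior <- array(FALSE, dim(img$voxels))
  interior[5:24, 5:24, 4:17] <- TRUE
  err <- abs(back$voxels - img$voxels)[interior]
  expect_lt(max(err), 0.02 * rng)
})

test_that("image and mask containers enforce their invariants", {
  expect_error(image3d(array(1, c(2, 2, 2)), spacing = c(0, 1, 1)), "positive")
  expect_error(image3d(matrix(1, 2, 2), spacing = c(1, 1, 1)), "3D")
  expect_error(slice2d(matrix(1, 2, 2), pixel_spacing = -1), "positive")
  img <- smooth_random_image()
  expect_error(roi_mask(array(2, dim(img$voxels)), img), "binary")
  expect_error(roi_mask(array(TRUE, c(2, 2, 2)), img), "shape")
  m <- roi_mask(img$voxels > 0, img)
  expect_equal(mask_volume(m), sum(img$voxels > 0) * prod(img$spacing))
  expect_error(landmark_set(c("a", "a"), rbind(c(0, 0), c(1, 1))),
               "duplicate")
})

test_that("transform_params and rotation_angle decompose similarities", {
  t <- compose(rigid_transform(c(0, 0, 0.3), shift = c(1, 2, 0)),
               scaling_transform(0.95, d = 3L))
  p <- transform_params(t)
  expect_equal(p$scales, rep(0.95, 3), tolerance = 1e-9)
  expect_equal(rotation_angle(t), 0.3, tolerance = 1e-9)
  t2 <- similarity_transform_2d(1.1, theta = 0.4, shift = c(1, -1))
  expect_equal(rotation_angle(t2), 0.4, tolerance = 1e-12)
})
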