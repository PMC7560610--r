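test_that("landmark errors are per-pair Euclidean distances in um", {
  a <- landmark_set(c("p", "q"), rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(unname(landmark_errors(a, a)), c(0, 0))
  b <- a; b$x <- b$x + 0.3
  expect_equal(unname(landmark_errors(a, b)), c(300, 300))
  set.seed(14)
  r1 <- landmark_set(paste0("l", 1:10), matrix(rnorm(30), 10, 3))
  r2 <- landmark_set(paste0("l", 1:10), matrix(rnorm(30), 10, 3))
  brute <- sapply(1:10, function(i)
    sqrt(sum((landmark_coords(r1)[i, ] - landmark_coords(r2)[i, ])^2)) * 1000)
  expect_equal(unname(landmark_errors(r1, r2)), brute)
  # transform applied to the first set, shuffled pairing by label
  t <- translation_transform(c(0.1, 0, 0))
  r2s <- r2[sample(10), ]
  class(r2s) <- class(r2)
  expect_equal(landmark_errors(r1, r2s, t)[r1$label],
               landmark_errors(r1, r2, t)[r1$label])
  bad <- landmark_set("z", rbind(c(0, 0, 0)))
  expect_error(landmark_errors(a, bad), "unmatched")
})

test_that("distance summaries follow the linear-interpolation convention", {
  s <- summarize_distances(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3); expect_equal(s$q25, 2); expect_equal(s$q75, 4)
  expect_equal(s$min, 1); expect_equal(s$max, 5)
  expect_equal(s$mean, 3); expect_equal(s$sd, sd(1:5)); expect_equal(s$n, 5L)
  one <- summarize_distances(7)
  expect_equal(one$median, 7); expect_equal(one$sd, 0)
  expect_false(one$sd_defined)
  set.seed(15)
  x <- rexp(31)
  expect_equal(unclass(summarize_distances(x)),
               unclass(summarize_distances(sample(x))))
  expect_error(summarize_distances(numeric(0)))
})

test_that("surface voxels follow face connectivity in 2D and 3D", {
  g3 <- image3d(array(0, c(5, 5, 5)), spacing = c(1, 1, 1))
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(nrow(surface_voxels(roi_mask(single, g3))), 1L)
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  expect_equal(nrow(surface_voxels(roi_mask(cube, g3))), 26L)
  g2 <- slice2d(matrix(0, 7, 7), pixel_spacing = c(1, 1))
  sq <- matrix(FALSE, 7, 7); sq[2:6, 2:6] <- TRUE
  expect_equal(nrow(surface_voxels(roi_mask(sq, g2))), 16L)
  # voxels at the array border count as surface (out-of-bounds neighbour)
  full <- roi_mask(matrix(TRUE, 3, 3), slice2d(matrix(0, 3, 3)))
  expect_equal(nrow(surface_voxels(full)), 8L)
  expect_error(surface_voxels(roi_mask(matrix(FALSE, 3, 3),
                                       slice2d(matrix(0, 3, 3)))), "empty")
})

test_that("surface distance matches analytic cases and is symmetric", {
  g <- image3d(array(0, c(12, 8, 8)), spacing = c(0.25, 0.25, 0.25))
  a <- array(FALSE, c(12, 8, 8)); a[3, 4, 4] <- TRUE
  b <- array(FALSE, c(12, 8, 8)); b[7, 4, 4] <- TRUE  # 4 voxels apart
  res <- surface_distance(roi_mask(a, g), roi_mask(b, g))
  expect_equal(unname(res$distances), c(1000, 1000))
  same <- surface_distance(roi_mask(a, g), roi_mask(a, g))
  expect_true(all(same$distances == 0))
  expect_equal(same$summary$median, 0)
  # pooled summary is symmetric in the arguments
  set.seed(16)
  ba <- random_blob(c(12, 10, 8)); bb <- random_blob(c(12, 10, 8))
  r1 <- surface_distance(roi_mask(ba, g <- image3d(array(0, c(12, 10, 8)),
                                                   spacing = c(0.3, 0.3, 0.3))),
                         roi_mask(bb, g))
  r2 <- surface_distance(roi_mask(bb, g), roi_mask(ba, g))
  expect_equal(sort(r1$distances), sort(r2$distances))
  expect_error(surface_distance(roi_mask(ba, g),
                                roi_mask(bb[, , 1:4],
                                         image3d(array(0, c(12, 10, 4)),
                                                 spacing = c(0.3, 0.3, 0.3)))),
               "resample")
})

test_that("surface distance equals the exhaustive oracle on random blobs", {
  set.seed(17)
  for (i in 1:10) {
    dims <- c(10, 9, 8)
    sp <- runif(3, 0.2, 0.5)
    g <- image3d(array(0, dims), spacing = sp)
    A <- roi_mask(random_blob(dims, sp), g)
    B <- roi_mask(random_blob(dims, sp), g)
    res <- surface_distance(A, B)
    to_phys <- function(m) {
      idx <- surface_voxels(m)
      sweep(sweep(idx - 1, 2, sp, `*`), 2, c(0, 0, 0), `+`)
    }
    Pa <- to_phys(A); Pb <- to_phys(B)
    expect_equal(res$a_to_b, oracle_min_dist(Pa, Pb) * 1000,
                 tolerance = 1e-12)
    expect_equal(res$b_to_a, oracle_min_dist(Pb, Pa) * 1000,
                 tolerance = 1e-12)
  }
})

test_that("surface distance is translation invariant; dilation zeroes one side", {
  set.seed(18)
  dims <- c(10, 10, 6); sp <- c(0.25, 0.25, 0.5)
  g0 <- image3d(array(0, dims), spacing = sp, origin = c(0, 0, 0))
  g1 <- image3d(array(0, dims), spacing = sp, origin = c(3, -2, 1))
  A <- random_blob(dims, sp); B <- random_blob(dims, sp)
  r0 <- surface_distance(roi_mask(A, g0), roi_mask(B, g0))
  r1 <- surface_distance(roi_mask(A, g1), roi_mask(B, g1))
  expect_equal(r0$distances, r1$distances)
  # B containing surface(A) in its surface band zeroes the A-side
  Bd <- A
  rA <- surface_distance(roi_mask(A, g0), roi_mask(Bd, g0))
  expect_true(all(rA$a_to_b == 0))
})

test_that("tumor ROI comparison reports volumes and respects the chain", {
  dims <- c(40, 40)
  sl <- slice2d(matrix(0, dims[1], dims[2]), pixel_spacing = c(0.1, 0.1),
                origin = c(0, 0))
  disk <- function(cx, cy, r) {
    idx <- which(matrix(TRUE, dims[1], dims[2]), arr.ind = TRUE)
    xs <- (idx[, 1] - 1) * 0.1; ys <- (idx[, 2] - 1) * 0.1
    matrix(sqrt((xs - cx)^2 + (ys - cy)^2) <= r, dims[1], dims[2])
  }
  A <- roi_mask(disk(2, 2, 1), sl)
  cmp <- compare_tumor_rois(A, A, identity_transform(2), slab_thickness = 1)
  expect_equal(cmp$surface$summary$median, 0)
  expect_equal(cmp$volume_mri_mm3, cmp$volume_fluor_mm3)
  # area of the disk within discretisation error of pi r^2 (x 1 mm slab)
  expect_lt(abs(cmp$volume_fluor_mm3 - pi), 0.15)
  # one-pixel erosion: median distance equals the in-plane spacing
  B <- roi_mask(disk(2, 2, 0.9), sl)
  cmp2 <- compare_tumor_rois(B, A, identity_transform(2))
  expect_equal(cmp2$surface$summary$median, 100, tolerance = 30)
  # the chain moves the ROI: translated disk through its inverse matches
  Ash <- roi_mask(disk(2.5, 2, 1), sl)
  chain <- translation_transform(c(0.5, 0))  # maps A's frame onto Ash's
  cmp3 <- compare_tumor_rois(A, Ash, chain)
  expect_equal(cmp3$surface$summary$median, 0)
})

test_that("volume percent difference follows the shrinkage sign convention", {
  g <- image3d(array(0, c(12, 12, 12)), spacing = c(0.5, 0.5, 0.5))
  m <- array(FALSE, c(12, 12, 12)); m[1:10, 1:10, 1:10] <- TRUE  # 1000 vox
  a <- roi_mask(m, g)
  expect_equal(volume_percent_difference(a, a), 0)
  m2 <- m; m2[which(m)[1:53]] <- FALSE                            # 947 vox
  expect_equal(volume_percent_difference(a, roi_mask(m2, g)), -5.3)
  # differing spacings handled in physical units:
  # 100 voxels at 0.5 mm iso = 12.5 mm^3 vs 800 voxels at 0.25 mm iso
  # = 12.5 mm^3 -> 0%
  gf <- image3d(array(0, c(20, 20, 20)), spacing = c(0.25, 0.25, 0.25))
  mc <- array(FALSE, c(12, 12, 12)); mc[1:10, 1:10, 1] <- TRUE
  mf <- array(FALSE, c(20, 20, 20)); mf[1:10, 1:10, 1:8] <- TRUE
  expect_equal(volume_percent_difference(roi_mask(mc, g), roi_mask(mf, gf)), 0)
  empty <- roi_mask(array(FALSE, c(12, 12, 12)), g)
  expect_error(volume_percent_difference(empty, a), "empty")
})
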