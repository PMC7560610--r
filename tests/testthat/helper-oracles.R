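# Independent oracles and small fixture builders shared across tests.
# Every oracle here is deliberately written by the most naive route
# available (double loops, normal equations, exhaustive scans) so it
# cannot share a failure mode with the implementation it checks.

# O(n^2) exhaustive nearest-neighbour distance, double loop.
oracle_min_dist <- function(A, B) {
  out <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# Closed-form 2D similarity fit via the linear normal equations in the
# (a, b, tx, ty) parameterisation of s*R = [a -b; b a]: an independent
# route to the least-squares optimum (no SVD).
oracle_similarity_ne <- function(X, Y) {
  n <- nrow(X)
  M <- matrix(0, 2 * n, 4)
  rhs <- numeric(2 * n)
  for (i in seq_len(n)) {
    M[2 * i - 1, ] <- c(X[i, 1], -X[i, 2], 1, 0)
    M[2 * i, ]     <- c(X[i, 2],  X[i, 1], 0, 1)
    rhs[2 * i - 1] <- Y[i, 1]
    rhs[2 * i]     <- Y[i, 2]
  }
  beta <- solve(crossprod(M), crossprod(M, rhs))
  a <- beta[1]; b <- beta[2]
  list(s = sqrt(a^2 + b^2), theta = atan2(b, a), t = c(beta[3], beta[4]))
}

# Exhaustive threshold search: smallest observed in-brain intensity that
# keeps every contralateral pixel out of the ROI.
oracle_threshold <- function(vals, brain, contra) {
  cand <- sort(unique(vals[brain]))
  for (t in cand) {
    roi <- brain & vals >= t
    if (!any(roi & contra)) return(list(threshold = t, roi = roi))
  }
  list(threshold = Inf, roi = brain & FALSE)
}

# Random connected-ish blob mask: a few overlapping balls on a grid.
random_blob <- function(dim, spacing = c(0.25, 0.25, 0.25), n_balls = 3,
                        grid_origin = c(0, 0, 0)) {
  arr <- array(FALSE, dim)
  idx <- which(arr | TRUE, arr.ind = TRUE)
  phys <- sweep(sweep(idx - 1, 2, spacing, `*`), 2, grid_origin, `+`)
  ext <- (dim - 1) * spacing
  for (b in seq_len(n_balls)) {
    c0 <- grid_origin + runif(3, 0.25, 0.75) * ext
    r <- runif(1, 0.15, 0.3) * min(ext)
    arr[sqrt(rowSums(sweep(phys, 2, c0)^2)) <= r] <- TRUE
  }
  if (!any(arr)) arr[ceiling(dim[1] / 2), ceiling(dim[2] / 2),
                     ceiling(dim[3] / 2)] <- TRUE
  arr
}

# Smooth random 3D test image (band-limited by construction).
smooth_random_image <- function(dim = c(24, 24, 16),
                                spacing = c(0.5, 0.5, 0.5), seed = 1,
                                sigma_vox = 2) {
  set.seed(seed)
  arr <- array(rnorm(prod(dim)), dim)
  arr <- multireg:::gaussian_blur(arr, rep(sigma_vox, 3))
  image3d(arr, spacing = spacing, modality = "test")
}

# Constellation of Gaussian blobs: a smooth image with distinct,
# non-repeating structure, so intensity registration has a unique
# optimum (smoothed white noise is too self-similar for that).
blob_image <- function(dim = c(26, 26, 18), spacing = c(0.5, 0.5, 0.5),
                       seed = 8, n = 12) {
  set.seed(seed)
  ax <- lapply(1:3, function(a) (seq_len(dim[a]) - 1) * spacing[a])
  g <- as.matrix(expand.grid(ax))
  ext <- (dim - 1) * spacing
  v <- numeric(nrow(g))
  for (i in seq_len(n)) {
    c0 <- runif(3, 0.2, 0.8) * ext
    sig <- runif(1, 0.5, 1.5)
    v <- v + runif(1, 0.5, 2) * exp(-rowSums(sweep(g, 2, c0)^2) / (2 * sig^2))
  }
  image3d(array(v, dim), spacing = spacing, modality = "blobs")
}

random_similarity_3d <- function(seed) {
  set.seed(seed)
  s <- runif(1, 0.8, 1.2)
  ang <- runif(3, -0.3, 0.3)
  sh <- runif(3, -2, 2)
  compose(rigid_transform(ang, shift = sh),
          scaling_transform(s, d = 3L))
}

random_landmarks_2d <- function(n = 6, seed = 1, space = "src") {
  set.seed(seed)
  landmark_set(paste0("p", seq_len(n)),
               cbind(runif(n, -5, 5), runif(n, -5, 5)), space = space)
}

# Cached expensive fixtures: the default synthetic study and its
# registrations are shared by the registration and acceptance tests.
.fixture_env <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- simulate_study(phantom_spec())
  .fixture_env$study
}

default_pipeline <- function() {
  if (is.null(.fixture_env$report)) {
    t0 <- Sys.time()
    .fixture_env$report <- run_pipeline(
      pipeline_config(spec = phantom_spec(), verbose = FALSE),
      study = default_study())
    .fixture_env$report_elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  }
  .fixture_env$report
}

rotation_error_deg <- function(recovered, truth) {
  dR <- t(truth$matrix[1:3, 1:3] / det(truth$matrix[1:3, 1:3])^(1 / 3)) %*%
    (recovered$matrix[1:3, 1:3] / det(recovered$matrix[1:3, 1:3])^(1 / 3))
  acos(pmin(1, pmax(-1, (sum(diag(dR)) - 1) / 2))) * 180 / pi
}
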