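#' Settings for intensity-based registration
#'
#' Controls the mutual-information (MI) registration driver. The MI
#' estimator is a plain joint histogram after percentile clipping of
#' intensities — no Parzen windowing — and the optimiser is
#' derivative-free Nelder-Mead over transform parameters, run
#' coarse-to-fine over the multiresolution levels, with optional
#' restarts jittered from `rng_seed`.
#'
#' @param dof Degrees of freedom: 6 (rigid) or 12 (full affine).
#' @param histogram_bins Joint-histogram bins per axis (>= 8, default 32).
#' @param max_iterations Nelder-Mead iteration cap per level.
#' @param tol_translation,tol_rotation,tol_scale Convergence scales:
#'   translation in mm, rotation in radians, scale as a fraction. The
#'   optimiser's relative tolerance is derived from the tightest of these.
#' @param tol_mi Minimum MI gain (nats) over the initial transform for
#'   the result to replace it; smaller gains are within the quantisation
#'   noise of the binned estimator, so the init is kept (with a
#'   warning). This is what makes self-registration return its
#'   initialisation exactly.
#' @param levels Multiresolution sampling strides, coarse to fine
#'   (default `c(4, 1)`: every 4th masked voxel, then all).
#' @param clip_percentiles Intensity clipping percentiles applied before
#'   binning (default 1st-99th).
#' @param n_restarts Optimiser starts per run; restarts beyond the first
#'   are jittered deterministically from `rng_seed`.
#' @param jitter_mm Translation jitter magnitude for restarts (mm).
#' @param presearch_mm Half-range of the translation-only grid search run
#'   before the simplex (mm; 0 disables). This stands in for the manual
#'   rough pre-alignment of the bench workflow and sets the capture
#'   range.
#' @param presearch_step Grid step of the pre-search (mm).
#' @param smooth_vox Gaussian pre-smoothing of both images before
#'   registration, in voxels of each image's own grid (default 0.5).
#'   Together with `sample_jitter` this suppresses the well-known
#'   grid-alignment interpolation artifacts of histogram MI.
#' @param sample_jitter Jitter MI sample positions uniformly within each
#'   masked voxel instead of sampling at voxel centres (default TRUE;
#'   deterministic given `rng_seed`).
#' @param rng_seed Seed for restart jitter (determinism guarantee).
#' @export
registration_settings <- function(dof = 6L, histogram_bins = 32L,
                                  max_iterations = 600L,
                                  tol_translation = 0.005,
                                  tol_rotation = 0.0005,
                                  tol_scale = 0.0005,
                                  tol_mi = 0.01,
                                  levels = c(4L, 1L),
                                  clip_percentiles = c(0.01, 0.99),
                                  n_restarts = 2L,
                                  jitter_mm = 0.25,
                                  presearch_mm = 2,
                                  presearch_step = 0.5,
                                  smooth_vox = 0.5,
                                  sample_jitter = TRUE,
                                  rng_seed = 1L) {
  stopifnot(dof %in% c(6L, 12L), histogram_bins >= 8L, length(levels) >= 1L,
            tol_translation > 0, tol_rotation > 0, tol_scale > 0,
            n_restarts >= 1L, presearch_mm >= 0)
  structure(list(dof = as.integer(dof),
                 histogram_bins = as.integer(histogram_bins),
                 max_iterations = as.integer(max_iterations),
                 tol_translation = tol_translation,
                 tol_rotation = tol_rotation, tol_scale = tol_scale,
                 tol_mi = tol_mi,
                 levels = as.integer(levels),
                 clip_percentiles = clip_percentiles,
                 n_restarts = as.integer(n_restarts),
                 jitter_mm = jitter_mm,
                 presearch_mm = presearch_mm,
                 presearch_step = presearch_step,
                 smooth_vox = smooth_vox,
                 sample_jitter = isTRUE(sample_jitter),
                 rng_seed = as.integer(rng_seed)),
            class = "registration_settings")
}

# Bin a vector of intensities into 1..bins over [lo, hi]; values outside
# the clipped range are clamped into the end bins so every sample counts.
bin_intensities <- function(v, lo, hi, bins) {
  if (hi <= lo) return(rep(1L, length(v)))
  b <- floor((v - lo) / (hi - lo) * bins) + 1L
  pmin.int(pmax.int(b, 1L), bins)
}

hist2d_counts <- function(ba, bb, bins) {
  h <- tabulate((ba - 1L) * bins + bb, nbins = bins * bins)
  matrix(h, nrow = bins, ncol = bins, byrow = TRUE)
}

#' Joint intensity histogram of two images over a mask
#'
#' The substrate of the MI objective: counts over `bins x bins` cells,
#' with bin edges spanning each image's masked intensity range after
#' percentile clipping. Out-of-range intensities are clamped into the
#' end bins, so the total count equals the number of masked voxels.
#'
#' @param a,b `image3d` (or `slice2d`) objects on the same grid — `b` is
#'   typically the resampled moving image.
#' @param mask `roi_mask` congruent with the grid; must be nonempty.
#' @param bins Bins per axis.
#' @param clip Clipping percentiles (default 1st-99th).
#' @return A `bins x bins` count matrix (rows index `a`'s bins).
#' @export
joint_histogram <- function(a, b, mask, bins = 32L, clip = c(0.01, 0.99)) {
  if (!same_grid(a, b) || !same_grid(a, mask))
    stop("joint_histogram requires both images and the mask on one grid")
  sel <- as.vector(mask$mask)
  if (!any(sel)) stop("empty mask")
  va <- as.vector(image_values(a))[sel]
  vb <- as.vector(image_values(b))[sel]
  ra <- stats::quantile(va, clip, names = FALSE, type = 7)
  rb <- stats::quantile(vb, clip, names = FALSE, type = 7)
  hist2d_counts(bin_intensities(va, ra[1], ra[2], bins),
                bin_intensities(vb, rb[1], rb[2], bins), bins)
}

#' Mutual information of a joint histogram, in nats
#'
#' `MI = sum p(i,j) log( p(i,j) / (p(i) p(j)) )` over nonzero cells;
#' always >= 0, and equal to the marginal entropy when the histogram is
#' diagonal (identical images).
#'
#' @param hist A 2D count (or probability) matrix with positive total.
#' @export
mutual_information <- function(hist) {
  tot <- sum(hist)
  if (!is.matrix(hist) || tot <= 0) stop("histogram must have positive total count")
  p <- hist / tot
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (outer(px, py)[nz])))
}

# Parameter vector -> pull-back delta transform about centre `cen`.
# Rigid: (tx,ty,tz, rx,ry,rz); affine: (tx,ty,tz, 9 entries of A) with
# linear part I + A. Zero parameters give the identity.
param_transform <- function(p, dof, cen) {
  if (dof == 6L) {
    rigid_transform(p[4:6], shift = p[1:3], center = cen)
  } else {
    L <- diag(3) + matrix(p[4:12], 3, 3)
    m <- diag(4)
    m[1:3, 1:3] <- L
    m[1:3, 4] <- cen - L %*% cen + p[1:3]
    affine_transform(m, kind = "affine")
  }
}

#' Mutual-information registration of two volumes over a fixed-image mask
#'
#' Maximises the MI between the fixed image and the moving image
#' resampled into its grid, evaluated only over `fixed_mask` voxels (the
#' paper-style phantom or brain mask). The search runs coarse-to-fine
#' over subsampled mask voxels, is deterministic given
#' `settings$rng_seed`, and starts from `init` — supply a manual rough
#' alignment when the images start far apart, as the capture range of
#' the MI objective is limited.
#'
#' @param moving,fixed `image3d` volumes (any grids; all geometry is in mm).
#' @param fixed_mask `roi_mask` on the fixed grid restricting the MI
#'   sample set.
#' @param settings A [registration_settings()].
#' @param init `affine_transform` mapping moving to fixed space
#'   (identity by default).
#' @param moving_mask Optional `roi_mask` on the moving grid; non-mask
#'   moving voxels are zeroed before sampling (the affine stage's
#'   brain-only restriction on the moving side).
#' @return The transform mapping the MOVING image's physical space to
#'   the FIXED image's (compose it with later stages; pass `invert()` of
#'   it to [resample()]). Attributes: `mi` (final MI, nats), `mi_init`,
#'   `log` (per-level optimiser summaries), and `improved` (FALSE, with
#'   a warning, when the optimiser could not beat `init`, in which case
#'   `init` is returned).
#' @export
register <- function(moving, fixed, fixed_mask, settings = registration_settings(),
                     init = NULL, moving_mask = NULL) {
  stopifnot(inherits(moving, "image3d"), inherits(fixed, "image3d"),
            inherits(fixed_mask, "roi_mask"))
  if (!same_grid(fixed, fixed_mask))
    stop("fixed_mask must share the fixed image's grid")
  if (!any(fixed_mask$mask)) stop("fixed_mask is empty")
  if (is.null(init)) init <- identity_transform(3L)
  if (!is.null(moving_mask)) {
    if (!same_grid(moving, moving_mask))
      stop("moving_mask must share the moving image's grid")
    moving <- image3d(moving$voxels * moving_mask$mask, moving$spacing,
                      moving$origin, moving$modality)
  }
  dof <- settings$dof
  bins <- settings$histogram_bins
  if (settings$smooth_vox > 0) {
    moving$voxels <- gaussian_blur(moving$voxels, rep(settings$smooth_vox, 3))
    fixed <- image3d(gaussian_blur(fixed$voxels, rep(settings$smooth_vox, 3)),
                     fixed$spacing, fixed$origin, fixed$modality)
  }
  idx <- which(fixed_mask$mask, arr.ind = TRUE)
  X_all <- sweep(sweep(idx - 1, 2, fixed$spacing, `*`), 2, fixed$origin, `+`)
  if (settings$sample_jitter) {
    # off-lattice sampling: draw each sample uniformly within its masked
    # voxel (fixed values interpolated there too)
    jit <- with_seed(settings$rng_seed + 101L,
                     matrix(stats::runif(length(X_all), -0.5, 0.5),
                            ncol = 3)) %*% diag(fixed$spacing)
    X_all <- X_all + jit
    fv_all <- sample_points(fixed, X_all, interp = "linear", background = 0)
  } else {
    fv_all <- fixed$voxels[fixed_mask$mask]
  }
  cen <- colMeans(X_all)
  radius <- mean(sqrt(rowSums(sweep(X_all, 2, cen)^2)))
  radius <- max(radius, 1)
  ra <- stats::quantile(fv_all, settings$clip_percentiles, names = FALSE)
  rb <- stats::quantile(as.vector(moving$voxels), settings$clip_percentiles,
                        names = FALSE)
  init_pb <- invert(init)  # pull-back: fixed -> moving
  # parameter scaling: one optimiser unit ~ 1 mm displacement at the
  # object radius
  parscale <- if (dof == 6L) c(rep(1, 3), rep(1 / radius, 3))
              else c(rep(1, 3), rep(1 / radius, 9))
  np <- length(parscale)
  reltol <- 1e-12
  jitters <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
            else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
    set.seed(settings$rng_seed)
    lapply(seq_len(settings$n_restarts), function(r)
      if (r == 1L) rep(0, np)
      else stats::rnorm(np, sd = settings$jitter_mm) * parscale)
  })
  make_obj <- function(X, fv, bins_lev = bins) {
    ba <- bin_intensities(fv, ra[1], ra[2], bins_lev)
    Xh <- cbind(X, 1)
    function(p) {
      Tm <- init_pb$matrix %*% param_transform(p, dof, cen)$matrix
      pts <- Xh %*% t(Tm[1:3, , drop = FALSE])
      mv <- sample_points(moving, pts, interp = "linear", background = 0)
      bb <- bin_intensities(mv, rb[1], rb[2], bins_lev)
      -mutual_information(hist2d_counts(ba, bb, bins_lev))
    }
  }
  log <- list()
  p <- rep(0, np)
  n_mask <- nrow(X_all)
  first_level <- TRUE
  for (lev in settings$levels) {
    # back off the stride on thin masks: MI needs a few hundred samples
    # to be a usable objective
    s <- lev
    repeat {
      keep <- rowSums((idx - 1) %% s) == 0
      if (sum(keep) >= min(300L, n_mask) || s == 1L) break
      s <- s %/% 2L
      if (s < 1L) s <- 1L
    }
    if (!any(keep))
      stop("fixed mask is empty after downsampling at stride ", lev)
    # with few samples a full-resolution histogram overfits (sparse
    # cells make MI spuriously high at wrong alignments); shrink the
    # bin count at subsampled levels so each cell sees ~5 samples
    bins_lev <- if (s > 1L)
      min(bins, max(8L, floor(sqrt(sum(keep) / 5)))) else bins
    obj <- make_obj(X_all[keep, , drop = FALSE], fv_all[keep], bins_lev)
    if (first_level && settings$presearch_mm > 0) {
      # translation-only grid search: the capture-range / rough-alignment
      # stage (the desk analogue of manual pre-alignment)
      g <- seq(-settings$presearch_mm, settings$presearch_mm,
               by = settings$presearch_step)
      grid <- as.matrix(expand.grid(g, g, g))
      vals <- apply(grid, 1, function(tr) obj(c(tr, rep(0, np - 3L))))
      p[1:3] <- grid[which.min(vals), ]
      log[[length(log) + 1L]] <- list(stage = "presearch", stride = s,
                                      n_samples = sum(keep),
                                      mi = -min(vals),
                                      iterations = nrow(grid))
    }
    # restarts (jittered) only at the coarsest level; finer levels refine
    # the single best candidate. Each start runs two consecutive simplex
    # sweeps -- the second rebuilds the simplex at the first's optimum,
    # escaping premature collapse.
    starts <- if (first_level) jitters else list(rep(0, np))
    best <- NULL
    iters <- 0L
    for (j in starts) {
      pj <- p + j
      prev <- Inf
      for (sweep_i in 1:6) {
        fit <- stats::optim(pj, obj, method = "Nelder-Mead",
                            control = list(maxit = settings$max_iterations,
                                           reltol = reltol,
                                           parscale = parscale))
        pj <- fit$par
        iters <- iters + fit$counts[["function"]]
        if (prev - fit$value < 1e-6) break  # simplex restart found nothing new
        prev <- fit$value
      }
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    p <- best$par
    log[[length(log) + 1L]] <- list(stage = "simplex", stride = s,
                                    n_samples = sum(keep),
                                    mi = -best$value,
                                    iterations = iters,
                                    convergence = best$convergence)
    first_level <- FALSE
  }
  # quasi-Newton polish at full resolution: the smoothed, jittered MI is
  # smooth enough for finite-difference gradients, and the simplex alone
  # under-converges in the 12-parameter affine case
  obj_full <- make_obj(X_all, fv_all)
  polish <- tryCatch(
    stats::optim(p, obj_full, method = "BFGS",
                 control = list(maxit = 100L, reltol = 1e-12,
                                parscale = parscale)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value < obj_full(p)) {
    p <- polish$par
    log[[length(log) + 1L]] <- list(stage = "polish", stride = 1L,
                                    n_samples = nrow(X_all),
                                    mi = -polish$value,
                                    iterations = polish$counts[["function"]])
  }
  mi_init <- -obj_full(rep(0, np))
  mi_final <- -obj_full(p)
  if (mi_final <= mi_init + (settings$tol_mi %||% 0.01)) {
    warning("optimiser did not improve on the initial transform; returning init")
    out <- init
    attr(out, "improved") <- FALSE
    attr(out, "mi") <- mi_init
  } else {
    pb <- compose(init_pb, param_transform(p, dof, cen))
    out <- invert(pb)
    attr(out, "improved") <- TRUE
    attr(out, "mi") <- mi_final
  }
  attr(out, "mi_init") <- mi_init
  attr(out, "log") <- log
  out
}

#' Rigid PET-to-MRI registration guided by the fiducial-loop phantom
#'
#' The multimodality-bed workflow: the water/tracer loop phantom is
#' visible in both PET and MRI, so MI is evaluated only inside
#' `phantom_mask` (on the MRI grid) and the search is restricted to 6
#' degrees of freedom. Manual rough pre-alignment is expected when the
#' initial offset is large (several mm); without it the optimiser may
#' return the init with a warning.
#'
#' @param pet,mri `image3d` volumes.
#' @param phantom_mask `roi_mask` on the MRI grid covering the loop.
#' @param settings [registration_settings()] (dof forced to 6).
#' @param init Initial PET-to-MRI transform (identity default).
#' @return List with `transform` (PET space -> MRI space, rigid),
#'   `pet_on_mri` (PET resampled onto the MRI grid), and the `mi`/`log`
#'   attributes of [register()] carried on the transform.
#' @export
register_pet_to_mri <- function(pet, mri, phantom_mask,
                                settings = registration_settings(),
                                init = NULL) {
  settings$dof <- 6L
  tr <- register(pet, mri, phantom_mask, settings = settings, init = init)
  list(transform = tr,
       pet_on_mri = resample(pet, invert(tr), mri, interp = "linear"))
}

#' Affine in-vivo to ex-vivo MRI registration over brain masks
#'
#' 12-degree-of-freedom registration absorbing the ~5% tissue shrinkage
#' from perfusion/fixation. MI is evaluated over the ex-vivo (fixed)
#' brain mask, which is what restricts the objective to brain voxels.
#' The in-vivo (moving) brain mask is accepted for interface parity with
#' the bench protocol (masks are drawn on both images) and validated,
#' but by default it does not modify the moving intensities:
#' hard-zeroing non-brain moving voxels stamps a mask-shaped pseudo-edge
#' into the image that measurably biases the recovered scale, so
#' `moving_mask_mode = "zero"` is opt-in. Compose the result onto a
#' PET-to-MRI transform to carry PET into ex-vivo space.
#'
#' @param invivo,exvivo `image3d` volumes.
#' @param brain_mask_in `roi_mask` on the in-vivo grid (moving side).
#' @param brain_mask_ex `roi_mask` on the ex-vivo grid (fixed side).
#' @param settings [registration_settings()] (dof forced to 12).
#' @param init Initial in-vivo-to-ex-vivo transform.
#' @param moving_mask_mode `"ignore"` (default) or `"zero"`.
#' @return List with `transform` (in-vivo space -> ex-vivo space, affine)
#'   and `invivo_on_exvivo`.
#' @export
register_invivo_to_exvivo <- function(invivo, exvivo, brain_mask_in,
                                      brain_mask_ex,
                                      settings = registration_settings(dof = 12L),
                                      init = NULL,
                                      moving_mask_mode = c("ignore", "zero")) {
  moving_mask_mode <- match.arg(moving_mask_mode)
  settings$dof <- 12L
  if (!any(brain_mask_in$mask) || !any(brain_mask_ex$mask))
    stop("both brain masks must be nonempty")
  if (!same_grid(invivo, brain_mask_in))
    stop("brain_mask_in must share the in-vivo grid")
  tr <- register(invivo, exvivo, brain_mask_ex, settings = settings,
                 init = init,
                 moving_mask = if (moving_mask_mode == "zero") brain_mask_in)
  list(transform = tr,
       invivo_on_exvivo = resample(invivo, invert(tr), exvivo, interp = "linear"))
}

#' Geometry of the pathology slice block
#'
#' Describes how the 1-mm slab slots of the slice block sit along the
#' ex-vivo MRI through-plane axis, so fluorescence slabs can be matched
#' to MRI slices.
#'
#' @param n_slots Number of slots in the block.
#' @param pitch Slot pitch in mm (default 1, the block's slice thickness).
#' @param face0 Through-plane physical coordinate (mm) of the face of
#'   slot 0 in ex-vivo MRI space.
#' @param mri_spacing MRI through-plane slice spacing in mm.
#' @param mri_origin Through-plane coordinate of the centre of MRI slice 1.
#' @param mri_n Number of MRI slices.
#' @export
slice_block_spec <- function(n_slots, pitch = 1, face0, mri_spacing,
                             mri_origin, mri_n) {
  stopifnot(pitch > 0, mri_spacing > 0, n_slots >= 1, mri_n >= 1)
  structure(list(n_slots = as.integer(n_slots), pitch = pitch, face0 = face0,
                 mri_spacing = mri_spacing, mri_origin = mri_origin,
                 mri_n = as.integer(mri_n)),
            class = "slice_block_spec")
}

#' Match pathology slabs to ex-vivo MRI slices via the slice block
#'
#' Slab `k` (0-based) occupies the through-plane interval
#' `[face0 + k * pitch, face0 + (k+1) * pitch)`. Every MRI slice whose
#' centre falls in that interval overlaps the slab; the representative
#' slice is the one whose centre is nearest the slab centre. With the
#' study's 1-mm slabs and 0.5-mm MRI slices each slab overlaps exactly
#' two slices, which is why the mapping keeps both views.
#'
#' @param block A [slice_block_spec()].
#' @param n_slabs Number of slabs cut (defaults to `block$n_slots`).
#' @return A data frame with one row per slab: `slab_index` (0-based),
#'   `representative` (1-based MRI slice index, NA if none), and a
#'   list-column `slices` of all overlapping slice indices. Slabs with
#'   no overlapping slice get an empty list and a warning.
#' @export
match_slices <- function(block, n_slabs = block$n_slots) {
  stopifnot(inherits(block, "slice_block_spec"))
  centers <- block$mri_origin + (seq_len(block$mri_n) - 1) * block$mri_spacing
  out <- data.frame(slab_index = seq_len(n_slabs) - 1L,
                    representative = NA_integer_)
  slices <- vector("list", n_slabs)
  for (k in seq_len(n_slabs)) {
    lo <- block$face0 + (k - 1L) * block$pitch
    hi <- lo + block$pitch
    inside <- which(centers >= lo & centers < hi)
    slices[[k]] <- inside
    if (!length(inside)) {
      warning("slab ", k - 1L, " lies outside the MRI extent")
    } else {
      out$representative[k] <- inside[which.min(abs(centers[inside] - (lo + hi) / 2))]
    }
  }
  out$slices <- slices
  out
}

#' Closed-form 2D landmark similarity fit (rigid plus uniform scaling)
#'
#' Least-squares estimate of scale `s`, rotation `theta` and translation
#' `t` minimising `sum || s R src_i + t - dst_i ||^2` over landmark
#' pairs matched by label — the per-slice registration of fluorescence
#' images to ex-vivo MRI slices from the six-point brain-edge protocol.
#' Reflections are excluded by sign-correcting the rotation determinant
#' (tissue slices cannot be mirror-imaged by slicing); set
#' `allow_reflection = TRUE` to also try a pre-flipped source for slabs
#' placed upside-down, keeping whichever fit has lower residual error.
#' Collinear landmark configurations are fine; fully coincident points
#' are rejected.
#'
#' @param src,dst 2D [landmark_set()]s with matching labels (>= 2
#'   non-coincident points).
#' @param allow_reflection Also try the x-flipped source (default FALSE).
#' @return Object of class `similarity_fit2d`: `transform` (2D
#'   similarity, src space -> dst space), `s`, `theta` (radians),
#'   `translation`, per-landmark `residuals` (mm, named), `rms` (mm),
#'   and `flipped`.
#' @export
fit_similarity_2d <- function(src, dst, allow_reflection = FALSE) {
  stopifnot(inherits(src, "landmark_set"), inherits(dst, "landmark_set"))
  if (!is.null(src$z) || !is.null(dst$z))
    stop("fit_similarity_2d requires 2D landmark sets")
  dst <- pair_landmarks(src, dst)
  X <- landmark_coords(src)
  Y <- landmark_coords(dst)
  n <- nrow(X)
  if (n < 2L) stop("at least 2 landmark pairs are required")
  if (max(abs(sweep(X, 2, colMeans(X)))) < 1e-12)
    stop("all source landmarks are coincident; similarity is underdetermined")
  fit_one <- function(X) {
    mx <- colMeans(X); my <- colMeans(Y)
    Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
    S <- crossprod(Yc, Xc) / n
    sv <- svd(S)
    D <- diag(2)
    if (det(sv$u %*% t(sv$v)) < 0) D[2, 2] <- -1
    R <- sv$u %*% D %*% t(sv$v)
    varx <- sum(Xc^2) / n
    s <- sum(diag(D) * sv$d) / varx
    if (s <= 0) s <- .Machine$double.eps
    t0 <- my - s * R %*% mx
    res <- Y - (s * X %*% t(R) + matrix(t0, n, 2, byrow = TRUE))
    list(s = s, R = R, t = as.numeric(t0), sse = sum(res^2), res = res)
  }
  f <- fit_one(X)
  flipped <- FALSE
  if (allow_reflection) {
    Xf <- X; Xf[, 1] <- -Xf[, 1]
    ff <- fit_one(Xf)
    if (ff$sse < f$sse) { f <- ff; flipped <- TRUE }
  }
  m <- diag(3)
  m[1:2, 1:2] <- f$s * f$R
  if (flipped) m[1:2, 1:2] <- m[1:2, 1:2] %*% diag(c(-1, 1))
  m[1:2, 3] <- f$t
  tr <- affine_transform(m, kind = if (flipped) "affine" else "similarity")
  resid <- sqrt(rowSums(f$res^2))
  names(resid) <- src$label
  structure(list(transform = tr, s = f$s,
                 theta = atan2(f$R[2, 1], f$R[1, 1]),
                 translation = f$t, residuals = resid,
                 rms = sqrt(mean(resid^2)), flipped = flipped, n = n),
            class = "similarity_fit2d")
}

#' @export
print.similarity_fit2d <- function(x, ...) {
  cat(sprintf(paste0("<similarity_fit2d> s = %.6f, theta = %.3f deg, ",
                     "t = (%.4f, %.4f) mm, rms = %.1f um over %d landmarks%s\n"),
              x$s, x$theta * 180 / pi, x$translation[1], x$translation[2],
              x$rms * 1000, x$n, if (x$flipped) " (pre-flipped)" else ""))
  invisible(x)
}

#' Register one fluorescence slab to its matched ex-vivo MRI slice
#'
#' Fits the 2D landmark similarity (fluorescence -> MRI slice space) and
#' resamples the fluorescence image onto the MRI slice grid; optionally
#' the reverse view, with the MRI slice upsampled onto the fluorescence
#' grid (the direction used before surface-distance comparison).
#'
#' @param slice Fluorescence [slice2d()].
#' @param mri_slice Matched ex-vivo MRI [slice2d()].
#' @param lm_fluor,lm_mri Paired 2D landmark sets in each image's
#'   physical space.
#' @param both_directions Also return `mri_on_fluor` (default TRUE).
#' @param allow_reflection Passed to [fit_similarity_2d()].
#' @return List with `fit` (the [fit_similarity_2d()] result),
#'   `transform` (fluorescence -> MRI space), `fluor_on_mri`, and
#'   optionally `mri_on_fluor`.
#' @export
register_fluorescence_slice <- function(slice, mri_slice, lm_fluor, lm_mri,
                                        both_directions = TRUE,
                                        allow_reflection = FALSE) {
  stopifnot(inherits(slice, "slice2d"), inherits(mri_slice, "slice2d"))
  fit <- fit_similarity_2d(lm_fluor, lm_mri, allow_reflection = allow_reflection)
  out <- list(fit = fit, transform = fit$transform,
              fluor_on_mri = resample(slice, invert(fit$transform), mri_slice,
                                      interp = "linear"))
  if (both_directions)
    out$mri_on_fluor <- resample(mri_slice, fit$transform, slice,
                                 interp = "linear")
  out
}
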