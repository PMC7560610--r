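#' Specification of the synthetic rodent-brain study
#'
#' Defines a digital phantom and simulated acquisitions for all four
#' modalities with known ground-truth transforms, so every registration
#' stage and agreement metric can be exercised with no animal data. The
#' anatomy is an ellipsoidal brain with two fluid-filled ventricles and
#' a tumor — either a circumscribed sphere (the "9L-like" growth
#' pattern) or a central blob with radiating filaments ("C6-like",
#' diffuse and infiltrative) — plus the water/tracer fiducial loop taped
#' to the bed below the head. Default geometry: in-vivo T2w grid at
#' 0.25 x 0.25 x 0.5 mm, PET at 0.5 mm isotropic with 1.5-mm FWHM
#' partial-volume blur, ex-vivo MRI related to in-vivo by a known
#' affine with ~5% uniform shrinkage, 1-mm slabs imaged at 34.4-um
#' pixels, each perturbed in-plane by a known similarity (rotation up to
#' +/-10 degrees, scale 0.95-1.05, translation up to +/-1 mm).
#'
#' @param tumor_type `"sphere"` (9L-like) or `"filaments"` (C6-like).
#' @param tumor_center,tumor_radius Tumor centre (mm, in-vivo space) and
#'   radius (mm). A zero radius gives a tumor-free phantom.
#' @param brain_center,brain_semiaxes Brain ellipsoid geometry (mm).
#' @param loop_center,loop_radius,loop_tube_diameter Fiducial loop torus
#'   geometry (mm); the loop lies in an axial plane under the head.
#' @param loop_warp Out-of-plane warp amplitude of the loop (mm). A
#'   hand-taped flexible tube is never perfectly planar; the warp (a
#'   `sin(2 phi)` vertical displacement around the loop) reproduces that
#'   and keeps all six rigid degrees of freedom observable from the
#'   loop alone.
#' @param loop_gap Angular gap (radians) where the bent tube's ends meet.
#' @param loop_tail Length (mm) of the straight tube ends running down
#'   the bed from the gap.
#' @param texture_amp Amplitude of the smooth intra-tissue T2 variation
#'   shared (through the shrinkage map) by in-vivo and ex-vivo MRI of
#'   the same brain.
#' @param mask_margin How generously the segmentation masks are drawn
#'   around their structures (mm), emulating a human placing a loose
#'   mask "around" the phantom or brain rather than tracing the exact
#'   boundary.
#' @param grid_dim,spacing In-vivo MRI grid (voxels; mm).
#' @param pet_dim,pet_spacing PET grid.
#' @param exvivo_dim Ex-vivo MRI grid (same spacing as in-vivo).
#' @param pet_shift,pet_angles True PET-to-MRI rigid: translation (mm)
#'   and Euler angles (radians).
#' @param shrink_scale,shrink_angle,shrink_shift True in-vivo-to-ex-vivo
#'   affine: uniform scale about the brain centre (0.95 = 5% linear
#'   shrinkage), rotation about z (radians), translation (mm).
#' @param slab_rot_range,slab_scale_range,slab_shift_range Per-slab
#'   in-plane perturbation ranges: rotation (radians), scale, shift (mm).
#' @param slab_thickness Slab pitch (mm).
#' @param fluor_pixel Fluorescence pixel size (mm).
#' @param noise Named list of Gaussian noise sd per modality
#'   (`mri`, `pet`, `fluor`), on intensity scales where tissue ~ 0.5-1.
#' @param pet_fwhm PET partial-volume blur FWHM (mm).
#' @param mri_blur,fluor_blur Acquisition partial-volume blur (Gaussian
#'   sigma, mm) applied to the MRI volumes and the fluorescence signal.
#' @param ventricles Include the ventricles (default TRUE).
#' @param rng_seed Seed; all outputs are deterministic given it.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(tumor_type = c("sphere", "filaments"),
                         tumor_center = c(2.6, -2.5, 1.8),
                         tumor_radius = 1.6,
                         brain_center = c(0, 0, 2),
                         brain_semiaxes = c(5.5, 8, 4.5),
                         loop_center = c(0, -1.5, -5),
                         loop_radius = 7, loop_tube_diameter = 3,
                         loop_warp = 1.0, loop_gap = 40 * pi / 180,
                         loop_tail = 5, texture_amp = 0.05,
                         mask_margin = 0.75,
                         grid_dim = c(96L, 112L, 32L),
                         spacing = c(0.25, 0.25, 0.5),
                         pet_dim = c(56L, 64L, 30L),
                         pet_spacing = c(0.5, 0.5, 0.5),
                         exvivo_dim = c(64L, 80L, 28L),
                         pet_shift = c(1.0, -0.5, 0.25),
                         pet_angles = c(0, 0, 2 * pi / 180),
                         shrink_scale = 0.95,
                         shrink_angle = 1 * pi / 180,
                         shrink_shift = c(0.2, -0.3, 0.1),
                         slab_rot_range = 10 * pi / 180,
                         slab_scale_range = c(0.95, 1.05),
                         slab_shift_range = 1.0,
                         slab_thickness = 1.0,
                         fluor_pixel = 0.0344,
                         noise = list(mri = 0.01, pet = 0.02, fluor = 0.01),
                         pet_fwhm = 1.5,
                         mri_blur = 0.3, fluor_blur = 0.15,
                         ventricles = TRUE,
                         rng_seed = 1L) {
  tumor_type <- match.arg(tumor_type)
  stopifnot(all(spacing > 0), all(pet_spacing > 0), slab_thickness > 0,
            fluor_pixel > 0, tumor_radius >= 0, shrink_scale > 0,
            all(slab_scale_range > 0), all(unlist(noise) >= 0))
  spec <- list(tumor_type = tumor_type, tumor_center = tumor_center,
               tumor_radius = tumor_radius, brain_center = brain_center,
               brain_semiaxes = brain_semiaxes, loop_center = loop_center,
               loop_radius = loop_radius,
               loop_tube_radius = loop_tube_diameter / 2,
               loop_warp = loop_warp, loop_gap = loop_gap,
               loop_tail = loop_tail, texture_amp = texture_amp,
               mask_margin = mask_margin,
               grid_dim = as.integer(grid_dim), spacing = spacing,
               pet_dim = as.integer(pet_dim), pet_spacing = pet_spacing,
               exvivo_dim = as.integer(exvivo_dim),
               pet_shift = pet_shift, pet_angles = pet_angles,
               shrink_scale = shrink_scale, shrink_angle = shrink_angle,
               shrink_shift = shrink_shift,
               slab_rot_range = slab_rot_range,
               slab_scale_range = slab_scale_range,
               slab_shift_range = slab_shift_range,
               slab_thickness = slab_thickness, fluor_pixel = fluor_pixel,
               noise = noise, pet_fwhm = pet_fwhm,
               mri_blur = mri_blur, fluor_blur = fluor_blur,
               ventricles = isTRUE(ventricles),
               rng_seed = as.integer(rng_seed),
               # tissue-class intensity levels per modality
               # (bg, brain, ventricle, tumor, loop)
               levels = list(
                 mri = c(0.03, 0.5, 0.9, 0.85, 1.0),
                 exvivo = c(0.15, 0.5, 0.9, 0.85, 0),
                 pet = c(0.02, 0.10, 0.10, 0.30, 1.0),
                 fluor = c(0, 0.08, 0.02, 1.0, 0)))
  # C6-like filaments: directions/lengths drawn once, frozen in the spec
  if (tumor_type == "filaments" && tumor_radius > 0) {
    spec$filaments <- with_seed(rng_seed + 1L, {
      nf <- 8L
      dirs <- matrix(stats::rnorm(3 * nf), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      list(dirs = dirs,
           lengths = stats::runif(nf, 0.8, 1.6) * tumor_radius,
           tube = 0.25)
    })
  }
  # tumor must sit inside the brain: the ellipsoid with semi-axes reduced
  # by r contains every centre whose r-sphere stays inside the brain
  if (tumor_radius > 0) {
    if (tumor_radius >= min(brain_semiaxes) ||
        sum(((tumor_center - brain_center) /
               (brain_semiaxes - tumor_radius))^2) > 1)
      stop("tumor extends outside the brain ellipsoid")
  }
  structure(spec, class = "phantom_spec")
}

# Run expr with a private RNG stream; the global RNG state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  expr
}

# Distance from points (n x 3) to a segment from a of direction d (unit),
# length L.
.seg_dist <- function(pts, a, d, L) {
  rel <- sweep(pts, 2, a)
  t <- pmin(pmax(rel %*% d, 0), L)
  sqrt(rowSums((rel - outer(as.numeric(t), d))^2))
}

# Tissue class at arbitrary physical points in the in-vivo (anatomy)
# frame: 0 bg, 1 brain, 2 ventricle, 3 tumor, 4 fiducial loop.
labels_at <- function(pts, spec) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
  lab <- integer(nrow(pts))
  el <- function(center, semi)
    rowSums(sweep(sweep(pts, 2, center), 2, semi, `/`)^2) <= 1
  lab[el(spec$brain_center, spec$brain_semiaxes)] <- 1L
  if (spec$ventricles %||% TRUE) {
    vents <- list(list(c(-1.2, 2.0, 2.3) + spec$brain_center - c(0, 0, 2),
                       c(0.5, 1.8, 0.7)),
                  list(c(1.2, 2.0, 2.3) + spec$brain_center - c(0, 0, 2),
                       c(0.5, 1.8, 0.7)))
    for (v in vents) lab[lab == 1L & el(v[[1]], v[[2]])] <- 2L
  }
  if (spec$tumor_radius > 0) {
    if (spec$tumor_type == "sphere") {
      inside <- sqrt(rowSums(sweep(pts, 2, spec$tumor_center)^2)) <=
        spec$tumor_radius
    } else {
      inside <- sqrt(rowSums(sweep(pts, 2, spec$tumor_center)^2)) <=
        0.45 * spec$tumor_radius
      fl <- spec$filaments
      for (i in seq_len(nrow(fl$dirs)))
        inside <- inside | .seg_dist(pts, spec$tumor_center, fl$dirs[i, ],
                                     fl$lengths[i]) <= fl$tube
    }
    lab[lab != 0L & inside] <- 3L
  }
  lab[loop_distance(pts, spec) <= spec$loop_tube_radius] <- 4L
  lab
}

# Smooth intra-tissue T2 variation tied to anatomical position: in-vivo
# and ex-vivo MRI image the same brain, so they share this texture
# (through the shrinkage map), just as real white/grey matter structure
# follows the tissue.
brain_texture <- function(pts, spec) {
  amp <- spec$texture_amp %||% 0.05
  if (amp == 0) return(numeric(nrow(pts)))
  amp * (sin(2.1 * pts[, 1] + 0.3) * cos(1.4 * pts[, 2] + 1.7) +
           cos(1.6 * pts[, 1] + 0.5) * sin(2.6 * pts[, 3] + 0.9) +
           sin(1.2 * pts[, 2] + 2.2) * cos(2.3 * pts[, 3] + 0.4))
}

# Distance to the loop centreline. The 8-cm flexible tube bent into a
# loop and taped to the bed is modelled as an open circular arc (the
# gap sits where the loop closes, on the tail side) whose two ends
# continue as straight segments running down the bed, with a
# sin(2*phi) vertical warp on the arc (a hand-taped tube is never
# perfectly planar). The gap, the tails and the warp make all six
# rigid degrees of freedom observable from the loop alone.
loop_distance <- function(pts, spec) {
  rel <- sweep(pts, 2, spec$loop_center)
  rxy <- sqrt(rel[, 1]^2 + rel[, 2]^2)
  gap <- spec$loop_gap %||% (40 * pi / 180)     # gap centred at phi = -pi/2
  tail_len <- spec$loop_tail %||% 6
  psi <- atan2(rel[, 2], rel[, 1]) + pi / 2     # 0 at the gap centre
  psi <- ((psi + pi) %% (2 * pi)) - pi
  psimax <- pi - gap / 2
  onarc <- abs(psi) <= psimax
  warp_z <- function(psi) spec$loop_warp * sin(2 * (psi - pi / 2))
  d <- rep(Inf, nrow(rel))
  d[onarc] <- sqrt((rxy[onarc] - spec$loop_radius)^2 +
                     (rel[onarc, 3] - warp_z(psi[onarc]))^2)
  for (sgn in c(-1, 1)) {
    a <- sgn * psimax - pi / 2                  # endpoint angle in phi
    endp <- c(spec$loop_radius * cos(a), spec$loop_radius * sin(a),
              warp_z(sgn * psimax))
    d <- pmin(d, .seg_dist(rel, endp, c(0, -1, 0), tail_len))
  }
  d
}

grid_points <- function(dim, spacing, origin) {
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dim[a]) - 1) * spacing[a])
  as.matrix(expand.grid(ax, KEEP.OUT.ATTRS = FALSE))
}

centered_origin <- function(dim, spacing, center = c(0, 0, 0))
  center - (dim - 1) * spacing / 2

#' Ground-truth transforms of a phantom spec
#'
#' @param spec A [phantom_spec()].
#' @return List with `pet_to_mri` (rigid, PET space to in-vivo MRI
#'   space) and `invivo_to_exvivo` (affine with the shrinkage scale,
#'   in-vivo to ex-vivo space).
#' @export
phantom_truth_transforms <- function(spec) {
  pet_to_mri <- rigid_transform(spec$pet_angles, shift = spec$pet_shift,
                                center = c(0, 0, 0))
  shrink <- compose(
    rigid_transform(c(0, 0, spec$shrink_angle), shift = spec$shrink_shift,
                    center = spec$brain_center),
    scaling_transform(spec$shrink_scale, d = 3L, center = spec$brain_center))
  shrink$kind <- "affine"
  list(pet_to_mri = pet_to_mri, invivo_to_exvivo = shrink)
}

#' Build the labelled tissue phantom
#'
#' Evaluates the phantom geometry on the in-vivo MRI grid and returns
#' the integer label volume (0 background, 1 brain, 2 ventricle, 3
#' tumor, 4 fiducial loop) with the tumor mask. Deterministic given the
#' spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `labels` ([image3d()] of integer classes) and
#'   `tumor_mask` ([roi_mask()]).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  origin <- centered_origin(spec$grid_dim, spec$spacing)
  lab <- array(labels_at(grid_points(spec$grid_dim, spec$spacing, origin), spec),
               dim = spec$grid_dim)
  labels <- image3d(lab, spacing = spec$spacing, origin = origin,
                    modality = "labels")
  list(labels = labels, tumor_mask = roi_mask(lab == 3L, labels))
}

#' Partition a volume into through-plane slabs with mean projection
#'
#' Emulates cutting the ex-vivo brain into 1-mm slices: contiguous slabs
#' along z starting at `face0`, each projected to a 2D image whose pixel
#' value is the mean of the member voxels through-plane (signal from the
#' whole optically cleared slab thickness contributes to the wide-field
#' image).
#'
#' @param vol An [image3d()].
#' @param thickness Slab thickness in mm; must be >= the through-plane
#'   spacing.
#' @param face0 Physical z of the first slab face (default: the lower
#'   face of the first slice).
#' @param n_slabs Number of slabs (default: as many as cover the volume).
#' @return List with `slices` (list of [slice2d()], slab_index 0-based),
#'   `intervals` (n x 2 matrix of slab faces, mm), and `face0`.
#' @export
slice_volume <- function(vol, thickness = 1, face0 = NULL, n_slabs = NULL) {
  stopifnot(inherits(vol, "image3d"))
  sz <- vol$spacing[3]
  if (thickness < sz - 1e-9)
    stop("slab thickness must be at least the through-plane spacing")
  centers <- vol$origin[3] + (seq_len(dim(vol$voxels)[3]) - 1) * sz
  if (is.null(face0)) face0 <- centers[1] - sz / 2
  if (is.null(n_slabs))
    n_slabs <- ceiling((centers[length(centers)] + sz / 2 - face0) / thickness)
  slices <- vector("list", n_slabs)
  intervals <- matrix(NA_real_, n_slabs, 2)
  for (k in seq_len(n_slabs)) {
    lo <- face0 + (k - 1) * thickness
    hi <- lo + thickness
    intervals[k, ] <- c(lo, hi)
    member <- which(centers >= lo & centers < hi)
    px <- if (length(member))
      apply(vol$voxels[, , member, drop = FALSE], c(1, 2), mean)
    else matrix(0, dim(vol$voxels)[1], dim(vol$voxels)[2])
    slices[[k]] <- slice2d(px, pixel_spacing = vol$spacing[1:2],
                           slab_thickness = thickness, slab_index = k - 1L,
                           origin = vol$origin[1:2], modality = vol$modality)
  }
  list(slices = slices, intervals = intervals, face0 = face0)
}

#' Simulate the complete four-modality study with known ground truth
#'
#' Produces the in-vivo T2w MRI (tumor and ventricles hyperintense,
#' fiducial loop bright), the PET volume on its coarser grid in a bed
#' frame offset by the true rigid (hypoxic tumor core and loop hot,
#' 1.5-mm FWHM blur, signal-scaled noise), the ex-vivo MRI related to
#' the in-vivo anatomy by the true shrinkage affine, and the
#' fluorescence slab images: the ex-vivo tumor-signal volume cut into
#' 1-mm slabs, mean-projected, resampled to 34.4-um pixels and each
#' perturbed by its true in-plane similarity, plus autofluorescence and
#' noise. All ground truths — transforms, masks, slab geometry, landmark
#' sets — are recorded.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `synthetic_study`: `invivo`, `pet`, `exvivo`
#'   ([image3d()]), `fluor_slabs` (list of [slice2d()]), `masks`
#'   (phantom loop, in-/ex-vivo brain, MRI tumor ROI, per-slab
#'   fluorescence brain and contralateral masks), `block`
#'   ([slice_block_spec()]), `landmarks` (per-slab six-point template in
#'   MRI-slice and fluorescence space, plus an independent evaluation
#'   set in in-vivo space with its true fluorescence positions), and
#'   `truth` (`pet_to_mri`, `invivo_to_exvivo`, per-slab `slab_similarity`
#'   mapping fluorescence to MRI-slice space, true tumor masks on every
#'   grid, slab-to-slice table).
#' @export
simulate_study <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  tt <- phantom_truth_transforms(spec)
  lv <- spec$levels
  ## ---- in-vivo MRI (bed/anatomy frame) ----
  origin_in <- centered_origin(spec$grid_dim, spec$spacing)
  pts_in <- grid_points(spec$grid_dim, spec$spacing, origin_in)
  lab_in <- labels_at(pts_in, spec)
  mk_img <- function(vals, dim, spacing, origin, blur_mm, modality) {
    arr <- array(vals, dim = dim)
    arr <- gaussian_blur(arr, blur_mm / spacing)
    image3d(arr, spacing, origin, modality)
  }
  add_texture <- function(vals, lab, pts) {
    tb <- lab == 1L
    vals[tb] <- vals[tb] + brain_texture(pts[tb, , drop = FALSE], spec)
    vals
  }
  invivo <- mk_img(add_texture(lv$mri[lab_in + 1L], lab_in, pts_in),
                   spec$grid_dim, spec$spacing, origin_in, spec$mri_blur, "T2w")
  ## ---- PET (bed frame offset by the true rigid) ----
  origin_pet <- centered_origin(spec$pet_dim, spec$pet_spacing)
  pts_pet <- grid_points(spec$pet_dim, spec$pet_spacing, origin_pet)
  anat_pet <- apply_transform(tt$pet_to_mri, pts_pet)
  lab_pet <- labels_at(anat_pet, spec)
  uptake <- lv$pet[lab_pet + 1L]
  if (spec$tumor_radius > 0) {
    core <- sqrt(rowSums(sweep(anat_pet, 2, spec$tumor_center)^2)) <=
      spec$tumor_radius / 2
    uptake[core] <- 1.0
  }
  pet <- mk_img(uptake, spec$pet_dim, spec$pet_spacing, origin_pet,
                spec$pet_fwhm / 2.355, "PET")
  ## ---- ex-vivo MRI (shrunken anatomy, loop removed) ----
  ex_center <- as.numeric(apply_transform(tt$invivo_to_exvivo,
                                          spec$brain_center))
  origin_ex <- centered_origin(spec$exvivo_dim, spec$spacing, ex_center)
  pts_ex <- grid_points(spec$exvivo_dim, spec$spacing, origin_ex)
  inv_shrink <- invert(tt$invivo_to_exvivo)
  anat_ex <- apply_transform(inv_shrink, pts_ex)
  lab_ex <- labels_at(anat_ex, spec)
  lab_ex[lab_ex == 4L] <- 0L  # the bed and loop do not travel with the brain
  exvivo <- mk_img(add_texture(lv$exvivo[lab_ex + 1L], lab_ex, anat_ex),
                   spec$exvivo_dim, spec$spacing, origin_ex, spec$mri_blur,
                   "T2w-exvivo")
  ## ---- masks ----
  # hand-drawn masks are generous: structures dilated by mask_margin
  mm <- spec$mask_margin
  in_ellipsoid <- function(pts, margin)
    rowSums(sweep(sweep(pts, 2, spec$brain_center), 2,
                  spec$brain_semiaxes + margin, `/`)^2) <= 1
  in_brain <- in_ellipsoid(pts_in, mm)
  ex_brain <- in_ellipsoid(anat_ex, mm)
  # the phantom ROI is drawn on the PET, where partial volume makes the
  # tube look wider, so it is about twice as generous as the brain masks
  loop_mask <- loop_distance(pts_in, spec) <= spec$loop_tube_radius + 2 * mm
  masks <- list(
    phantom = roi_mask(array(loop_mask, spec$grid_dim), invivo),
    brain_in = roi_mask(array(in_brain, spec$grid_dim), invivo),
    brain_ex = roi_mask(array(ex_brain, spec$exvivo_dim), exvivo),
    mri_tumor = roi_mask(array(lab_in == 3L, spec$grid_dim), invivo))
  tumor_mask_ex <- roi_mask(array(lab_ex == 3L, spec$exvivo_dim), exvivo)
  ## ---- fluorescence slabs ----
  fl_arr <- array(lv$fluor[lab_ex + 1L], spec$exvivo_dim)
  if (spec$fluor_blur > 0)
    fl_arr <- gaussian_blur(fl_arr, spec$fluor_blur / spec$spacing)
  fluor_vol <- image3d(fl_arr, spec$spacing, origin_ex, "tdTomato")
  ez <- which(apply(array(ex_brain, spec$exvivo_dim), 3, any))
  zc <- origin_ex[3] + (ez - 1) * spec$spacing[3]
  face0 <- min(zc) - spec$spacing[3] / 2
  n_slabs <- ceiling((max(zc) + spec$spacing[3] / 2 - face0) /
                       spec$slab_thickness)
  sl <- slice_volume(fluor_vol, spec$slab_thickness, face0 = face0,
                     n_slabs = n_slabs)
  tumor_sl <- slice_volume(image3d(array(as.numeric(lab_ex == 3L),
                                         spec$exvivo_dim),
                                   spec$spacing, origin_ex, "tumor"),
                           spec$slab_thickness, face0 = face0,
                           n_slabs = n_slabs)
  block <- slice_block_spec(n_slots = n_slabs, pitch = spec$slab_thickness,
                            face0 = face0, mri_spacing = spec$spacing[3],
                            mri_origin = origin_ex[3],
                            mri_n = spec$exvivo_dim[3])
  ## per-slab true similarity (fluorescence -> MRI-slice space) and grids
  slab_sim <- with_seed(spec$rng_seed + 2L, lapply(seq_len(n_slabs), function(k) {
    invert(similarity_transform_2d(
      s = stats::runif(1, spec$slab_scale_range[1], spec$slab_scale_range[2]),
      theta = stats::runif(1, -spec$slab_rot_range, spec$slab_rot_range),
      shift = stats::runif(2, -spec$slab_shift_range, spec$slab_shift_range),
      center = ex_center[1:2]))
  }))
  margin <- 3
  f_dim <- ceiling(((spec$exvivo_dim[1:2] - 1) * spec$spacing[1:2] +
                      2 * margin) / spec$fluor_pixel) + 1
  f_origin <- origin_ex[1:2] - margin
  f_template <- slice2d(matrix(0, f_dim[1], f_dim[2]),
                        pixel_spacing = rep(spec$fluor_pixel, 2),
                        slab_thickness = spec$slab_thickness,
                        origin = f_origin)
  fluor_slabs <- vector("list", n_slabs)
  fluor_brain <- vector("list", n_slabs)
  fluor_contra <- vector("list", n_slabs)
  fluor_tumor_true <- vector("list", n_slabs)
  ax_f <- list(f_origin[1] + (seq_len(f_dim[1]) - 1) * spec$fluor_pixel,
               f_origin[2] + (seq_len(f_dim[2]) - 1) * spec$fluor_pixel)
  pts_f <- as.matrix(expand.grid(ax_f, KEEP.OUT.ATTRS = FALSE))
  for (k in seq_len(n_slabs)) {
    z_mid <- face0 + (k - 0.5) * spec$slab_thickness
    # a fluorescence pixel at x_f sees slab tissue at S_k(x_f) in MRI
    # in-plane coordinates
    sim <- slab_sim[[k]]
    img_k <- resample(sl$slices[[k]], sim, f_template, interp = "linear")
    img_k$slab_index <- k - 1L
    img_k$modality <- "tdTomato"
    tum_k <- resample(tumor_sl$slices[[k]], sim, f_template, interp = "linear")
    # brain / contralateral membership evaluated through the true chain
    mri_xy <- apply_transform(sim, pts_f)
    anat <- apply_transform(inv_shrink,
                            cbind(mri_xy, z_mid))
    in_brain_f <- rowSums(sweep(sweep(anat, 2, spec$brain_center), 2,
                                spec$brain_semiaxes, `/`)^2) <= 1
    side <- sign(spec$tumor_center[1] - spec$brain_center[1])
    if (side == 0) side <- 1
    # tumor-free hemisphere, with a 0.5-mm guard band at the midline
    contra_f <- in_brain_f &
      side * (anat[, 1] - spec$brain_center[1]) < -0.5
    fluor_brain[[k]] <- roi_mask(array(in_brain_f, f_dim), img_k)
    fluor_contra[[k]] <- roi_mask(array(contra_f, f_dim), img_k)
    fluor_tumor_true[[k]] <- roi_mask(array(tum_k$pixels >= 0.5, f_dim), img_k)
    fluor_slabs[[k]] <- img_k
  }
  ## ---- landmarks ----
  landmarks <- make_study_landmarks(spec, tt, block, slab_sim, n_slabs)
  ## ---- noise, deterministically seeded ----
  study_noise <- function() {
    if (spec$noise$mri > 0) {
      invivo$voxels <<- invivo$voxels +
        array(stats::rnorm(length(invivo$voxels), sd = spec$noise$mri),
              dim(invivo$voxels))
      exvivo$voxels <<- exvivo$voxels +
        array(stats::rnorm(length(exvivo$voxels), sd = spec$noise$mri),
              dim(exvivo$voxels))
    }
    if (spec$noise$pet > 0) {
      # scaled-Gaussian stand-in for Poisson counting noise: sd grows
      # with the square root of local signal
      amp <- spec$noise$pet * sqrt(pmax(pet$voxels, 0) / max(pet$voxels) + 0.05)
      pet$voxels <<- pet$voxels +
        amp * array(stats::rnorm(length(pet$voxels)), dim(pet$voxels))
    }
    if (spec$noise$fluor > 0) {
      for (k in seq_len(n_slabs))
        fluor_slabs[[k]]$pixels <<- fluor_slabs[[k]]$pixels +
          matrix(stats::rnorm(length(fluor_slabs[[k]]$pixels),
                              sd = spec$noise$fluor),
                 nrow = nrow(fluor_slabs[[k]]$pixels))
    }
  }
  with_seed(spec$rng_seed + 3L, study_noise())
  slab_table <- suppressWarnings(match_slices(block, n_slabs))
  structure(list(
    spec = spec, invivo = invivo, pet = pet, exvivo = exvivo,
    fluor_slabs = fluor_slabs,
    masks = c(masks, list(fluor_brain = fluor_brain,
                          fluor_contra = fluor_contra)),
    block = block, landmarks = landmarks,
    truth = list(pet_to_mri = tt$pet_to_mri,
                 invivo_to_exvivo = tt$invivo_to_exvivo,
                 slab_similarity = slab_sim,
                 tumor_mask_in = masks$mri_tumor,
                 tumor_mask_ex = tumor_mask_ex,
                 fluor_tumor = fluor_tumor_true,
                 slab_table = slab_table)),
    class = "synthetic_study")
}

#' Degenerate phantom spec: noise-free with identity ground truths
#'
#' The fully degenerate study condition used to verify that the pipeline
#' is exact when there is nothing to recover: no acquisition noise, no
#' partial-volume blur, no tissue texture, no ventricles, and every true
#' transform equal to the identity. Under these conditions the
#' registrations return the identity exactly, landmark errors are all
#' zero, and tumor ROIs thresholded on the MRI-contrast and
#' fluorescence-contrast slab projections coincide pixel for pixel.
#'
#' @param ... Overrides forwarded to [phantom_spec()].
#' @export
phantom_spec_degenerate <- function(...) {
  s <- phantom_spec(noise = list(mri = 0, pet = 0, fluor = 0),
                    texture_amp = 0, mri_blur = 0, fluor_blur = 0,
                    ventricles = FALSE,
                    pet_shift = c(0, 0, 0), pet_angles = c(0, 0, 0),
                    shrink_scale = 1, shrink_angle = 0,
                    shrink_shift = c(0, 0, 0),
                    slab_rot_range = 0, slab_scale_range = c(1, 1),
                    slab_shift_range = 0, ...)
  # with an identity shrinkage the ex-vivo scan images the unchanged
  # tissue, so it shares the in-vivo intensity map exactly; its grid is
  # then a sub-grid of the in-vivo one and identity is the exact MI
  # optimum of the affine stage
  s$levels$exvivo <- s$levels$mri
  s
}

# Six-point per-slab template (4 brain-edge + 2 midline points) plus an
# independent 4-point evaluation set per slab, with true positions in
# every space of the chain.
make_study_landmarks <- function(spec, tt, block, slab_sim, n_slabs) {
  inv_shrink <- invert(tt$invivo_to_exvivo)
  bc <- spec$brain_center
  ba <- spec$brain_semiaxes
  per_slab <- vector("list", n_slabs)
  for (k in seq_len(n_slabs)) {
    z_mid <- block$face0 + (k - 0.5) * block$pitch
    # in-vivo z of the slab mid-plane, via the inverse shrinkage
    z0 <- apply_transform(inv_shrink, c(bc[1], bc[2], z_mid))[3]
    h <- (z0 - bc[3]) / ba[3]
    if (abs(h) > 0.92) next  # slab grazes the brain pole; no template
    f <- sqrt(1 - h^2)
    a <- ba[1] * f; b <- ba[2] * f
    ang <- c(45, 135, 225, 315) * pi / 180
    edge <- cbind(bc[1] + a * cos(ang), bc[2] + b * sin(ang))
    midline <- cbind(bc[1] + c(0, 0), bc[2] + c(0.9 * b, -0.9 * b))
    tmpl_in <- cbind(rbind(edge, midline), z0)
    lab6 <- c("edge_ne", "edge_nw", "edge_sw", "edge_se",
              "midline_a", "midline_p")
    ev_ang <- c(0, 90, 180, 270) * pi / 180
    ev_in <- cbind(bc[1] + 0.72 * a * cos(ev_ang),
                   bc[2] + 0.72 * b * sin(ev_ang), z0)
    lab4 <- c("eval_r", "eval_a", "eval_l", "eval_p")
    to_mri_plane <- function(P) {
      q <- apply_transform(tt$invivo_to_exvivo, P)
      q[, 1:2, drop = FALSE]
    }
    tm <- to_mri_plane(tmpl_in)
    em <- to_mri_plane(ev_in)
    inv_sim <- invert(slab_sim[[k]])
    per_slab[[k]] <- list(
      slab_index = k - 1L,
      template_invivo = landmark_set(lab6, tmpl_in, space = "invivo"),
      template_mri = landmark_set(lab6, tm, space = "exvivo_slice"),
      template_fluor = landmark_set(lab6, apply_transform(inv_sim, tm),
                                    space = sprintf("fluor_slab%02d", k - 1L)),
      eval_invivo = landmark_set(lab4, ev_in, space = "invivo"),
      eval_fluor_true = landmark_set(lab4, apply_transform(inv_sim, em),
                                     space = sprintf("fluor_slab%02d", k - 1L)))
  }
  per_slab
}
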