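#' Extract one through-plane slice of a volume as a 2D image
#'
#' @param vol An [image3d()].
#' @param k 1-based slice index along z.
#' @param slab_thickness,slab_index Metadata for the resulting slice.
#' @return A [slice2d()] on the volume's in-plane grid.
#' @export
extract_slice <- function(vol, k, slab_thickness = 1, slab_index = 0L) {
  stopifnot(inherits(vol, "image3d"), k >= 1, k <= dim(vol$voxels)[3])
  slice2d(vol$voxels[, , k], pixel_spacing = vol$spacing[1:2],
          slab_thickness = slab_thickness, slab_index = slab_index,
          origin = vol$origin[1:2], modality = vol$modality)
}

#' Configuration of a full pipeline run
#'
#' @param spec A [phantom_spec()] describing the synthetic study to
#'   simulate, or NULL when `study` is supplied to [run_pipeline()]
#'   directly.
#' @param settings_rigid,settings_affine [registration_settings()] for
#'   the PET and in-vivo-to-ex-vivo stages.
#' @param output_dir Directory for reports and stage outputs (NULL: keep
#'   everything in memory only).
#' @param write_volumes Also write resampled volumes and transforms
#'   (needs `output_dir`).
#' @param verbose Print stage progress.
#' @export
pipeline_config <- function(spec = phantom_spec(),
                            settings_rigid = registration_settings(),
                            settings_affine = registration_settings(dof = 12L),
                            output_dir = NULL,
                            write_volumes = FALSE,
                            verbose = TRUE) {
  structure(list(spec = spec, settings_rigid = settings_rigid,
                 settings_affine = settings_affine,
                 output_dir = output_dir, write_volumes = write_volumes,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full co-registration and validation pipeline
#'
#' Executes the complete chain on a study: rigid PET-to-MRI registration
#' over the phantom mask; 12-DOF affine in-vivo-to-ex-vivo registration
#' over the brain masks; slab-to-slice matching through the slice-block
#' geometry; per-slab 2D landmark similarity registration of the
#' fluorescence images; threshold segmentation of the fluorescence tumor
#' signal; and the agreement metrics (landmark-error summaries, surface
#' distances between the MRI-derived and fluorescence-derived tumor
#' ROIs on the fluorescence grid, brain-volume change, tumor volumes).
#' Deterministic given the study and settings seeds.
#'
#' @param config A [pipeline_config()].
#' @param study A `synthetic_study` from [simulate_study()]; when NULL,
#'   one is simulated from `config$spec`.
#' @return A list of class `pipeline_report`; see Details.
#'
#' @details The report contains `transforms` (recovered PET-to-MRI,
#'   in-vivo-to-ex-vivo, their composition, and per-slab similarities),
#'   `slabs` (a per-slab data frame: similarity parameters, fit RMS,
#'   threshold, ROI pixel counts, surface-distance median, volumes),
#'   `landmark_eval` (full-chain in-vivo-to-fluorescence error summary),
#'   `surface_pooled` (pooled surface-distance summary across slabs),
#'   `volumes` (brain and tumor volumes and percent differences), and
#'   `timings`.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  tic <- function() Sys.time()
  timings <- list()
  if (is.null(study)) {
    say("simulating synthetic study (seed %d)", config$spec$rng_seed)
    t0 <- tic(); study <- simulate_study(config$spec)
    timings$simulate <- as.numeric(Sys.time() - t0, units = "secs")
  }
  stopifnot(inherits(study, "synthetic_study"))

  say("stage 1/5: rigid PET -> in-vivo MRI (phantom mask)")
  t0 <- tic()
  pet_res <- register_pet_to_mri(study$pet, study$invivo,
                                 study$masks$phantom, config$settings_rigid)
  timings$register_pet <- as.numeric(Sys.time() - t0, units = "secs")

  say("stage 2/5: affine in-vivo -> ex-vivo MRI (brain masks)")
  t0 <- tic()
  aff_res <- register_invivo_to_exvivo(study$invivo, study$exvivo,
                                       study$masks$brain_in,
                                       study$masks$brain_ex,
                                       config$settings_affine)
  timings$register_affine <- as.numeric(Sys.time() - t0, units = "secs")
  pet_to_exvivo <- compose(aff_res$transform, pet_res$transform)

  say("stage 3/5: slab-to-slice matching")
  slab_table <- suppressWarnings(match_slices(study$block))

  say("stage 4/5: per-slab fluorescence registration + segmentation")
  t0 <- tic()
  n_slabs <- length(study$fluor_slabs)
  slab_rows <- list()
  slab_fits <- vector("list", n_slabs)
  eval_err <- numeric(0)
  surf_all <- numeric(0)
  surf_by_slab <- list()
  mri_tumor_ex <- resample(study$masks$mri_tumor, invert(aff_res$transform),
                           study$exvivo)
  mri_tumor_img <- image3d(array(as.numeric(mri_tumor_ex$mask),
                                 dim(mri_tumor_ex$mask)),
                           study$exvivo$spacing, study$exvivo$origin, "roi")
  tum_slabs <- slice_volume(mri_tumor_img, study$block$pitch,
                            face0 = study$block$face0, n_slabs = n_slabs)
  for (k in seq_len(n_slabs)) {
    lm <- study$landmarks[[k]]
    rep_k <- slab_table$representative[k]
    if (is.null(lm) || is.na(rep_k)) next
    mri_slice <- extract_slice(study$exvivo, rep_k,
                               slab_thickness = study$block$pitch,
                               slab_index = k - 1L)
    reg <- register_fluorescence_slice(study$fluor_slabs[[k]], mri_slice,
                                       lm$template_fluor, lm$template_mri,
                                       both_directions = FALSE)
    slab_fits[[k]] <- reg$fit
    seg <- threshold_segment(study$fluor_slabs[[k]],
                             study$masks$fluor_brain[[k]],
                             study$masks$fluor_contra[[k]])
    ## full-chain evaluation landmarks: in-vivo -> ex-vivo (recovered
    ## affine) -> in-plane -> fluorescence (recovered slab similarity)
    ev3 <- apply_transform(aff_res$transform, landmark_coords(lm$eval_invivo))
    ev2 <- landmark_set(lm$eval_invivo$label, ev3[, 1:2, drop = FALSE],
                        space = "exvivo_slice")
    ev_f <- apply_transform(invert(reg$transform), ev2)
    err_k <- landmark_errors(ev_f, lm$eval_fluor_true)
    eval_err <- c(eval_err, err_k)
    ## tumor ROI agreement on the fluorescence grid
    mri_slab_roi <- roi_mask(tum_slabs$slices[[k]]$pixels >= 0.5,
                             tum_slabs$slices[[k]])
    srow <- list(slab_index = k - 1L, mri_slice = rep_k,
                 s = reg$fit$s, theta_deg = reg$fit$theta * 180 / pi,
                 fit_rms_um = reg$fit$rms * 1000,
                 threshold = seg$threshold,
                 n_roi_px = seg$n_roi_voxels,
                 eval_err_med_um = stats::median(err_k),
                 surf_median_um = NA_real_,
                 vol_mri_mm3 = NA_real_, vol_fluor_mm3 = NA_real_)
    if (any(mri_slab_roi$mask) && seg$n_roi_voxels > 0) {
      cmp <- compare_tumor_rois(mri_slab_roi, seg$roi,
                                chain = invert(reg$transform),
                                slab_thickness = study$block$pitch)
      srow$surf_median_um <- cmp$surface$summary$median
      srow$vol_mri_mm3 <- cmp$volume_mri_mm3
      srow$vol_fluor_mm3 <- cmp$volume_fluor_mm3
      surf_all <- c(surf_all, cmp$surface$distances)
      surf_by_slab[[as.character(k - 1L)]] <- cmp$surface$distances
    }
    slab_rows[[length(slab_rows) + 1L]] <- srow
  }
  timings$slabs <- as.numeric(Sys.time() - t0, units = "secs")
  slabs <- do.call(rbind, lapply(slab_rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))

  say("stage 5/5: volume metrics and report")
  brain_vol_diff <- volume_percent_difference(study$masks$brain_in,
                                              study$masks$brain_ex)
  tum_rows <- slabs[!is.na(slabs$vol_mri_mm3), , drop = FALSE]
  volumes <- list(
    brain_in_mm3 = mask_volume(study$masks$brain_in),
    brain_ex_mm3 = mask_volume(study$masks$brain_ex),
    brain_volume_diff_pct = brain_vol_diff,
    tumor_mri_mm3 = sum(tum_rows$vol_mri_mm3),
    tumor_fluor_mm3 = sum(tum_rows$vol_fluor_mm3))
  report <- structure(list(
    transforms = list(pet_to_mri = pet_res$transform,
                      invivo_to_exvivo = aff_res$transform,
                      pet_to_exvivo = pet_to_exvivo,
                      slab_similarity = slab_fits),
    slabs = slabs,
    slab_table = slab_table,
    landmark_eval = summarize_distances(eval_err),
    surface_pooled = if (length(surf_all)) summarize_distances(surf_all),
    surface_by_slab = surf_by_slab,
    volumes = volumes,
    timings = timings,
    seed = study$spec$rng_seed),
    class = "pipeline_report")
  if (!is.null(config$output_dir))
    write_report(report, config$output_dir, study = study,
                 write_volumes = config$write_volumes)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  full-chain landmark error: "); print(x$landmark_eval)
  if (!is.null(x$surface_pooled)) {
    cat("  pooled tumor surface distance: "); print(x$surface_pooled)
  }
  cat(sprintf("  brain volume change: %+.1f%%\n",
              x$volumes$brain_volume_diff_pct))
  cat(sprintf("  tumor volume MRI %.1f mm^3 vs fluorescence %.1f mm^3\n",
              x$volumes$tumor_mri_mm3, x$volumes$tumor_fluor_mm3))
  cat(sprintf("  %d slabs processed\n",
              if (is.null(x$slabs)) 0L else nrow(x$slabs)))
  invisible(x)
}

#' Box plot of per-slab tumor surface distances
#'
#' One box per tumor-bearing slab, distances in micrometres, with the
#' per-slab median marked in red and whiskers at the full range — the
#' standard presentation of cross-modality tumor-margin agreement.
#'
#' @param report A `pipeline_report` (or a named list of distance
#'   vectors in um).
#' @param ... Passed on to [graphics::boxplot()].
#' @return The boxplot statistics, invisibly.
#' @export
plot_surface_distances <- function(report, ...) {
  dists <- if (inherits(report, "pipeline_report"))
    report$surface_by_slab else report
  if (!length(dists)) stop("no surface-distance measurements to plot")
  bp <- graphics::boxplot(dists, range = 0, xlab = "slab index",
                          ylab = "surface distance (µm)", ...)
  meds <- vapply(dists, stats::median, numeric(1))
  graphics::points(seq_along(dists), meds, col = "red", pch = 19)
  invisible(bp)
}

#' Write a pipeline report (and optionally stage outputs) to disk
#'
#' Writes `report.csv` (per-slab rows), `summary.csv` (the headline
#' metrics), recovered transforms as plain-text files, and — with
#' `write_volumes = TRUE` — the resampled volumes as NIfTI.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if missing).
#' @param study Optionally the study, to write resampled volumes.
#' @param write_volumes Write NIfTI stage outputs too.
#' @export
write_report <- function(report, dir, study = NULL, write_volumes = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$slabs))
    utils::write.csv(report$slabs, file.path(dir, "report.csv"),
                     row.names = FALSE)
  le <- as.data.frame(report$landmark_eval)
  le$metric <- "landmark_error_um"
  summ <- le
  if (!is.null(report$surface_pooled)) {
    sp <- as.data.frame(report$surface_pooled)
    sp$metric <- "surface_distance_um"
    summ <- rbind(summ, sp)
  }
  utils::write.csv(summ, file.path(dir, "summary.csv"), row.names = FALSE)
  write_transform(report$transforms$pet_to_mri,
                  file.path(dir, "pet_to_mri.txt"))
  write_transform(report$transforms$invivo_to_exvivo,
                  file.path(dir, "invivo_to_exvivo.txt"))
  write_transform(report$transforms$pet_to_exvivo,
                  file.path(dir, "pet_to_exvivo.txt"))
  for (k in seq_along(report$transforms$slab_similarity)) {
    f <- report$transforms$slab_similarity[[k]]
    if (!is.null(f))
      write_transform(f$transform,
                      file.path(dir, sprintf("slab%02d_similarity.txt", k - 1L)))
  }
  vols <- data.frame(name = names(report$volumes),
                     value = unlist(report$volumes))
  utils::write.csv(vols, file.path(dir, "volumes.csv"), row.names = FALSE)
  if (write_volumes && !is.null(study)) {
    write_volume(study$invivo, file.path(dir, "invivo.nii.gz"))
    write_volume(study$exvivo, file.path(dir, "exvivo.nii.gz"))
    write_volume(study$pet, file.path(dir, "pet.nii.gz"))
  }
  invisible(dir)
}

#' Write a simulated study to disk as a portable layout
#'
#' Volumes as NIfTI, fluorescence slabs as TIFF, masks as NIfTI,
#' per-slab landmark CSVs, true transforms as text, and a `layout.yaml`
#' indexing everything — the on-disk form consumed by the command-line
#' interface. Slabs whose signal lies in [0, 1] are stored as lossless
#' 32-bit float TIFF; noisy slabs (which dip below 0) are quantised to
#' 16-bit counts spanning the study's dynamic range, the same
#' quantisation a real wide-field acquisition applies.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(study$invivo, file.path(dir, "invivo_mri.nii.gz"))
  write_volume(study$pet, file.path(dir, "pet.nii.gz"))
  write_volume(study$exvivo, file.path(dir, "exvivo_mri.nii.gz"))
  mask_vol <- function(m) image3d(array(as.numeric(m$mask), dim(m$mask)),
                                  m$spacing, m$origin, "mask")
  write_volume(mask_vol(study$masks$phantom), file.path(dir, "mask_phantom.nii.gz"))
  write_volume(mask_vol(study$masks$brain_in), file.path(dir, "mask_brain_invivo.nii.gz"))
  write_volume(mask_vol(study$masks$brain_ex), file.path(dir, "mask_brain_exvivo.nii.gz"))
  write_volume(mask_vol(study$masks$mri_tumor), file.path(dir, "mask_tumor_mri.nii.gz"))
  slab_files <- character(0)
  rng <- range(vapply(study$fluor_slabs, function(s) range(s$pixels),
                      numeric(2)))
  quantise <- rng[1] < 0 || rng[2] > 1
  for (k in seq_along(study$fluor_slabs)) {
    f <- sprintf("fluor_slab%02d.tif", k - 1L)
    sl <- study$fluor_slabs[[k]]
    if (quantise)
      sl$pixels <- round(pmax(sl$pixels, 0) * (65535 / max(rng[2], 1e-12)))
    write_slice(sl, file.path(dir, f))
    slab_files <- c(slab_files, f)
    lm <- study$landmarks[[k]]
    if (!is.null(lm)) {
      write_landmarks(lm$template_mri,
                      file.path(dir, sprintf("landmarks_mri_slab%02d.csv", k - 1L)))
      write_landmarks(lm$template_fluor,
                      file.path(dir, sprintf("landmarks_fluor_slab%02d.csv", k - 1L)))
    }
  }
  write_transform(study$truth$pet_to_mri, file.path(dir, "true_pet_to_mri.txt"))
  write_transform(study$truth$invivo_to_exvivo,
                  file.path(dir, "true_invivo_to_exvivo.txt"))
  layout <- list(invivo_mri = "invivo_mri.nii.gz", pet = "pet.nii.gz",
                 exvivo_mri = "exvivo_mri.nii.gz",
                 fluor_slabs = as.list(slab_files),
                 fluor_slab_index = as.list(seq_along(slab_files) - 1L),
                 fluor_pixel_spacing = study$spec$fluor_pixel,
                 slab_pitch = study$block$pitch,
                 slab_face0 = study$block$face0,
                 masks = list(phantom = "mask_phantom.nii.gz",
                              brain_invivo = "mask_brain_invivo.nii.gz",
                              brain_exvivo = "mask_brain_exvivo.nii.gz",
                              tumor_mri = "mask_tumor_mri.nii.gz"))
  yaml::write_yaml(layout, file.path(dir, "layout.yaml"))
  invisible(dir)
}
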