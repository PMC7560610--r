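#' Per-landmark registration error
#'
#' Euclidean distance, per label, between the transformed points of `a`
#' and their counterparts in `b` — the accuracy protocol in which a
#' fresh set of landmarks is placed in both spaces and compared after
#' registration. Pass `t = NULL` (identity) when the coordinates are
#' already in a common space.
#'
#' @param a,b Paired [landmark_set()]s (matching labels).
#' @param t Optional `affine_transform` mapping `a`'s space to `b`'s.
#' @return Named numeric vector of distances in micrometres.
#' @export
landmark_errors <- function(a, b, t = NULL) {
  stopifnot(inherits(a, "landmark_set"), inherits(b, "landmark_set"))
  b <- pair_landmarks(a, b)
  pa <- landmark_coords(a)
  if (!is.null(t)) pa <- apply_transform(t, pa)
  pb <- landmark_coords(b)
  if (ncol(pa) != ncol(pb)) stop("landmark sets have different dimension")
  d <- sqrt(rowSums((pa - pb)^2)) * 1000
  names(d) <- a$label
  d
}

#' Summary statistics of a set of distances
#'
#' The reporting format of the accuracy protocol: median, interquartile
#' range, full range, mean and sd, with percentiles computed by linear
#' interpolation between order statistics (R's default type-7 rule,
#' fixed so summaries are reproducible). A single distance gives sd 0
#' with `sd_defined = FALSE`.
#'
#' @param distances Numeric vector (micrometres by convention), n >= 1.
#' @return Object of class `distance_summary` with fields `median`,
#'   `q25`, `q75`, `min`, `max`, `mean`, `sd`, `n`, `sd_defined`.
#' @export
summarize_distances <- function(distances) {
  distances <- as.numeric(distances)
  if (!length(distances) || any(!is.finite(distances)))
    stop("need at least one finite distance")
  q <- stats::quantile(distances, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(median = q[2], q25 = q[1], q75 = q[3],
                 min = min(distances), max = max(distances),
                 mean = mean(distances),
                 sd = if (length(distances) > 1L) stats::sd(distances) else 0,
                 n = length(distances),
                 sd_defined = length(distances) > 1L),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf(paste0("<distance_summary> median %.0f um, IQR %.0f-%.0f um, ",
                     "range %.0f-%.0f um, mean %.0f (sd %.0f), n = %d\n"),
              x$median, x$q25, x$q75, x$min, x$max, x$mean, x$sd, x$n))
  invisible(x)
}

#' @export
as.data.frame.distance_summary <- function(x, ...) {
  data.frame(median = x$median, q25 = x$q25, q75 = x$q75, min = x$min,
             max = x$max, mean = x$mean, sd = x$sd, n = x$n)
}

#' Surface voxels of a binary ROI
#'
#' Foreground voxels with at least one face-adjacent background (or
#' out-of-bounds) neighbour: 6-connectivity in 3D, 4-connectivity in 2D.
#'
#' @param roi A nonempty [roi_mask()].
#' @return Integer matrix of 1-based voxel indices (one row per surface
#'   voxel).
#' @export
surface_voxels <- function(roi) {
  stopifnot(inherits(roi, "roi_mask"))
  m <- roi$mask
  if (!any(m)) stop("empty ROI has no surface")
  d <- dim(m)
  nd <- length(d)
  surf <- array(FALSE, d)
  for (a in seq_len(nd)) for (s in c(-1L, 1L)) {
    nb <- shift_array(m, a, s, fill = FALSE)  # neighbour's foreground state
    surf <- surf | (m & !nb)
  }
  which(surf, arr.ind = TRUE)
}

# Shift a logical/numeric array by s along axis a, filling vacated cells.
shift_array <- function(arr, a, s, fill = FALSE) {
  d <- dim(arr)
  idx <- rep(list(quote(expr = )), length(d))
  out <- array(fill, d)
  src <- seq_len(d[a])
  dst <- src + s
  ok <- dst >= 1L & dst <= d[a]
  idx_src <- idx; idx_src[[a]] <- src[ok]
  idx_dst <- idx; idx_dst[[a]] <- dst[ok]
  out_idx <- do.call(`[<-`, c(list(out), idx_dst,
                              list(do.call(`[`, c(list(arr), idx_src,
                                                  list(drop = FALSE))))))
  out_idx
}

# Exact nearest-neighbour distances (mm) from each row of A to the set B,
# chunked to bound memory. Squared distances are accumulated per
# coordinate as (a_k - b_k)^2 rather than through the expanded inner
# product, so values are exact (no cancellation) and zero for
# coincident points.
min_cross_dist <- function(A, B, chunk = 512L) {
  out <- numeric(nrow(A))
  for (start in seq(1L, nrow(A), by = chunk)) {
    sel <- start:min(start + chunk - 1L, nrow(A))
    d2 <- outer(A[sel, 1], B[, 1], `-`)^2
    for (k in 2:ncol(A)) d2 <- d2 + outer(A[sel, k], B[, k], `-`)^2
    out[sel] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Symmetric surface distance between two ROIs on a common grid
#'
#' For every voxel on the surface of ROI A, the minimum physical
#' distance (between voxel centres, using the grid spacing) to any
#' voxel on the surface of ROI B — and vice versa, with both direction
#' sets pooled into one distribution, since the protocol summarises
#' "across all voxels on the surfaces" of both ROIs. Distances are exact
#' nearest-neighbour values, reported in micrometres. The ROIs must
#' share a grid: resample one first (the bench protocol upsamples the
#' MRI ROI to the fluorescence grid).
#'
#' @param roi_a,roi_b Nonempty [roi_mask()]s on the same grid.
#' @param symmetric Pool both directions (default TRUE); otherwise only
#'   A-surface-to-B distances are returned.
#' @return List with `distances` (pooled, um), `summary`
#'   ([summarize_distances()]), and the per-direction vectors `a_to_b`,
#'   `b_to_a`.
#' @export
surface_distance <- function(roi_a, roi_b, symmetric = TRUE) {
  stopifnot(inherits(roi_a, "roi_mask"), inherits(roi_b, "roi_mask"))
  if (!same_grid(roi_a, roi_b))
    stop("ROIs are on different grids; resample() one onto the other's grid first")
  sa <- surface_voxels(roi_a)
  sb <- surface_voxels(roi_b)
  to_phys <- function(idx, m)
    sweep(sweep(idx - 1, 2, m$spacing, `*`), 2, m$origin, `+`)
  Pa <- to_phys(sa, roi_a)
  Pb <- to_phys(sb, roi_b)
  a_to_b <- min_cross_dist(Pa, Pb) * 1000
  b_to_a <- if (symmetric) min_cross_dist(Pb, Pa) * 1000 else numeric(0)
  pooled <- c(a_to_b, b_to_a)
  list(distances = pooled, summary = summarize_distances(pooled),
       a_to_b = a_to_b, b_to_a = b_to_a)
}

#' Cross-modality tumor ROI comparison
#'
#' Brings the (manual) MRI tumor ROI into the fluorescence frame through
#' the composed registration chain, computes the symmetric surface
#' distance against the fluorescence-defined ROI on the fluorescence
#' grid, and reports both ROI volumes. `chain` maps MRI physical space
#' to fluorescence physical space; the MRI ROI is resampled with
#' nearest-neighbour interpolation (mask-safe).
#'
#' @param mri_roi [roi_mask()] on the MRI(-derived) grid.
#' @param fluor_roi [roi_mask()] on the fluorescence grid.
#' @param chain `affine_transform` from MRI space to fluorescence space
#'   (identity if already aligned). Must match the masks' dimension
#'   (use the in-plane 2D chain for per-slab comparisons).
#' @param slab_thickness For 2D masks, the slab thickness (mm) used to
#'   convert areas to volumes (default 1).
#' @return List with `surface` (the [surface_distance()] result),
#'   `volume_mri_mm3`, `volume_fluor_mm3`, and `mri_roi_on_fluor`.
#' @export
compare_tumor_rois <- function(mri_roi, fluor_roi, chain = NULL,
                               slab_thickness = 1) {
  stopifnot(inherits(mri_roi, "roi_mask"), inherits(fluor_roi, "roi_mask"))
  d <- length(dim(fluor_roi$mask))
  if (is.null(chain)) chain <- identity_transform(d)
  moved <- if (same_grid(mri_roi, fluor_roi) &&
               max(abs(chain$matrix - diag(d + 1L))) < 1e-12)
    mri_roi
  else resample(mri_roi, invert(chain), fluor_roi)
  vol_factor <- if (d == 2L) slab_thickness else 1
  list(surface = surface_distance(moved, fluor_roi),
       volume_mri_mm3 = mask_volume(moved) * vol_factor,
       volume_fluor_mm3 = mask_volume(fluor_roi) * vol_factor,
       mri_roi_on_fluor = moved)
}

#' Percent volume difference between two ROIs
#'
#' `100 * (V_ex - V_in) / V_in` with each volume computed on its own
#' grid (voxel count times voxel volume); negative values mean
#' shrinkage from the in-vivo to the ex-vivo state, matching the sign
#' convention of the brain-volume change report.
#'
#' @param roi_in Reference (in-vivo) [roi_mask()], nonempty.
#' @param roi_ex Comparison (ex-vivo) [roi_mask()].
#' @return Percent difference (scalar).
#' @export
volume_percent_difference <- function(roi_in, roi_ex) {
  stopifnot(inherits(roi_in, "roi_mask"), inherits(roi_ex, "roi_mask"))
  v_in <- mask_volume(roi_in)
  if (v_in <= 0) stop("reference ROI is empty")
  100 * (mask_volume(roi_ex) - v_in) / v_in
}
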