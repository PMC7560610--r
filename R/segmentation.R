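#' Threshold-based tumor segmentation against a contralateral reference
#'
#' The semi-automatic rule for defining the tumor ROI on a fluorescence
#' slab: choose the lowest intensity threshold such that no voxel of the
#' contralateral (tumor-free) hemisphere enters the ROI. Operationally,
#' the threshold is the smallest observed brain-mask intensity strictly
#' greater than the contralateral maximum (for float images, one ulp
#' above that maximum when no such observed value exists), and the ROI
#' is every brain-mask pixel with intensity >= threshold — which
#' excludes the contralateral pixels by construction. The interactive
#' selection of the bench protocol is replaced by this deterministic
#' rule.
#'
#' @param slice A [slice2d()] (or [image3d()]) of fluorescence signal.
#' @param brain_mask `roi_mask` of the brain on the same grid.
#' @param contralateral_mask `roi_mask` of the tumor-free reference
#'   region; must be nonempty and contained in `brain_mask`.
#' @param largest_component Keep only the largest 4-connected component
#'   of the ROI (default FALSE).
#' @return Object of class `threshold_result`: `roi` ([roi_mask()]),
#'   `threshold`, `contralateral_max`, `n_roi_voxels`.
#' @export
threshold_segment <- function(slice, brain_mask, contralateral_mask,
                              largest_component = FALSE) {
  if (!same_grid(slice, brain_mask) || !same_grid(slice, contralateral_mask))
    stop("masks must share the image grid")
  if (!any(brain_mask$mask)) stop("brain mask is empty")
  if (!any(contralateral_mask$mask))
    stop("contralateral mask is empty; the threshold is undefined without it")
  if (any(contralateral_mask$mask & !brain_mask$mask))
    stop("contralateral mask must be contained in the brain mask")
  v <- image_values(slice)
  cmax <- max(v[contralateral_mask$mask])
  vb <- v[brain_mask$mask]
  above <- vb[vb > cmax]
  thr <- if (length(above)) min(above) else cmax + max(abs(cmax), 1) * .Machine$double.eps * 2
  roi_arr <- brain_mask$mask & v >= thr
  if (largest_component && any(roi_arr))
    roi_arr <- largest_connected_component(roi_arr)
  stopifnot(!any(roi_arr & contralateral_mask$mask))  # invariant by construction
  structure(list(roi = roi_mask(roi_arr, brain_mask),
                 threshold = thr, contralateral_max = cmax,
                 n_roi_voxels = sum(roi_arr)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> t* = %.6g (contralateral max %.6g), %d ROI voxels\n",
    x$threshold, x$contralateral_max, x$n_roi_voxels))
  invisible(x)
}

# Largest face-connected component of a logical array (2D or 3D),
# iterative flood fill.
largest_connected_component <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  labels <- array(0L, d)
  nxt <- 0L
  strides <- cumprod(c(1, d[-nd]))
  todo <- which(mask & labels == 0L)
  for (seed in todo) {
    if (labels[seed] != 0L) next
    nxt <- nxt + 1L
    queue <- seed
    labels[seed] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      ci <- arrayInd(cur, d)
      for (a in seq_len(nd)) for (s in c(-1L, 1L)) {
        ni <- ci
        ni[, a] <- ni[, a] + s
        ok <- ni[, a] >= 1L & ni[, a] <= d[a]
        if (!any(ok)) next
        lin <- as.integer((ni[ok, , drop = FALSE] - 1L) %*% strides + 1L)
        lin <- lin[mask[lin] & labels[lin] == 0L]
        if (length(lin)) {
          labels[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
      queue <- unique(queue)
    }
  }
  if (nxt == 0L) return(mask)
  sizes <- tabulate(labels[labels > 0L], nbins = nxt)
  labels == which.max(sizes)
}

#' Load a manually drawn ROI mask and validate it against a grid
#'
#' The in-vivo MRI tumor ROI is a manual input in this workflow (drawn
#' around the hyperintense tumor, excluding ventricles), not computed;
#' this reads it from NIfTI or TIFF/PNG and checks shape congruence and
#' binarity. An all-zero mask (no visible tumor) is accepted with a
#' warning.
#'
#' @param path Mask file (`.nii`/`.nii.gz`/`.tif`/`.png`).
#' @param grid The [image3d()] or [slice2d()] whose grid the mask must
#'   match.
#' @return A [roi_mask()].
#' @export
manual_roi_load <- function(path, grid) {
  vals <- if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    read_volume(path)$voxels
  else read_slice(path)$pixels
  g <- grid_of(grid)
  if (!identical(dim(vals), as.integer(g$dim)))
    stop("mask in ", path, " has shape ", paste(dim(vals), collapse = "x"),
         " but the target grid is ", paste(g$dim, collapse = "x"))
  u <- unique(as.vector(vals))
  if (!all(u %in% c(0, 1)))
    stop("mask in ", path, " is not binary (values beyond 0/1)")
  if (all(vals == 0)) warning("mask in ", path, " is empty (no tumor voxels)")
  roi_mask(vals == 1, grid)
}

#' Maximum intensity projection of a confocal z-stack
#'
#' Collapses an ordered stack of congruent slices to a single 2D image
#' by per-pixel maximum, the standard reduction of confocal z-stacks
#' for visualisation and analysis.
#'
#' @param stack List of congruent [slice2d()]s (or plain matrices).
#' @return A [slice2d()] carrying the first slice's grid metadata.
#' @export
max_intensity_projection <- function(stack) {
  if (!length(stack)) stop("empty stack")
  first <- stack[[1]]
  px <- lapply(stack, function(s) if (inherits(s, "slice2d")) s$pixels else as.matrix(s))
  dims <- vapply(px, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("stack slices are not congruent")
  out <- Reduce(pmax, px)
  if (inherits(first, "slice2d")) {
    first$pixels <- out
    first$modality <- paste0(first$modality, if (nzchar(first$modality)) "-MIP" else "MIP")
    first
  } else slice2d(out)
}

#' Contralateral mask by mirroring across a midline
#'
#' Helper standing in for the hand-drawn contralateral reference: keeps
#' the part of `brain_mask` on the far side of the midline plane
#' `x = midline` (axis 1) from the tumor, optionally with a guard band.
#'
#' @param brain_mask A [roi_mask()].
#' @param midline Physical coordinate (mm) of the midline along `axis`.
#' @param tumor_side `+1` if the tumor lies at coordinates above the
#'   midline, `-1` below.
#' @param axis Axis of the left-right direction (default 1).
#' @param guard Guard band excluded around the midline, mm (default 0.5).
#' @export
mirror_contralateral <- function(brain_mask, midline, tumor_side = 1,
                                 axis = 1L, guard = 0.5) {
  stopifnot(inherits(brain_mask, "roi_mask"), tumor_side %in% c(-1, 1))
  d <- dim(brain_mask$mask)
  coord <- brain_mask$origin[axis] + (seq_len(d[axis]) - 1) * brain_mask$spacing[axis]
  keep <- tumor_side * (coord - midline) < -guard
  sel <- array(FALSE, d)
  idx <- slice.index(sel, axis)
  sel[] <- keep[idx]
  structure(list(mask = brain_mask$mask & sel, spacing = brain_mask$spacing,
                 origin = brain_mask$origin),
            class = "roi_mask")
}
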