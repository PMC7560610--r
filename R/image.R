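#' 3D scalar image on an axis-aligned physical grid
#'
#' Voxel index `(i, j, k)` (1-based in R) sits at physical coordinate
#' `origin + (i - 1, j - 1, k - 1) * spacing`, i.e. `origin` is the
#' centre of the first voxel and coordinates refer to voxel centres.
#' The internal axis order is (x, y, z) = (left-right,
#' posterior-anterior, inferior-superior); readers reorder on load.
#' Oblique (direction-cosine) grids are not represented.
#'
#' @param voxels Non-empty numeric 3D array.
#' @param spacing Length-3 positive voxel spacing in mm.
#' @param origin Physical position (mm) of the centre of voxel (1,1,1).
#' @param modality Free-text modality tag (e.g. "T2w", "PET").
#' @return An object of class `image3d`.
#' @export
image3d <- function(voxels, spacing, origin = c(0, 0, 0), modality = "") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L || length(voxels) == 0L)
    stop("voxels must be a non-empty 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  stopifnot(length(origin) == 3L)
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), modality = modality),
            class = "image3d")
}

#' @export
print.image3d <- function(x, ...) {
  cat(sprintf("<image3d> %s  dims %s  spacing %s mm  origin %s mm\n",
              if (nzchar(x$modality)) x$modality else "(untagged)",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' 2D slice image with physical pixel grid and slab metadata
#'
#' Represents one 1-mm pathology slab imaged in fluorescence (or one MRI
#' slice extracted for comparison). Pixel `(i, j)` sits at
#' `origin + (i - 1, j - 1) * pixel_spacing`.
#'
#' @param pixels Non-empty numeric 2D matrix.
#' @param pixel_spacing Length-2 positive pixel size in mm (default the
#'   IVIS bin-1 pixel, 34.4 um).
#' @param slab_thickness Slab thickness in mm (default 1, the slice-block
#'   pitch).
#' @param slab_index Integer position of the slab in the slice block
#'   (0-based, slab 0 at the block face).
#' @param origin In-plane physical position (mm) of pixel (1,1) centre.
#' @param modality Free-text tag.
#' @export
slice2d <- function(pixels, pixel_spacing = c(0.0344, 0.0344),
                    slab_thickness = 1, slab_index = 0L,
                    origin = c(0, 0), modality = "") {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L) stop("pixels must be a non-empty matrix")
  pixel_spacing <- rep(as.numeric(pixel_spacing), length.out = 2L)
  if (any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0))
    stop("pixel_spacing must be strictly positive (mm)")
  if (!is.finite(slab_thickness) || slab_thickness <= 0)
    stop("slab_thickness must be strictly positive (mm)")
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing,
                 slab_thickness = as.numeric(slab_thickness),
                 slab_index = as.integer(slab_index),
                 origin = as.numeric(origin), modality = modality),
            class = "slice2d")
}

#' @export
print.slice2d <- function(x, ...) {
  cat(sprintf(
    "<slice2d> %s  %dx%d px  %s mm/px  slab %d (%.2f mm thick)\n",
    if (nzchar(x$modality)) x$modality else "(untagged)",
    nrow(x$pixels), ncol(x$pixels),
    paste(signif(x$pixel_spacing, 4), collapse = "x"),
    x$slab_index, x$slab_thickness))
  invisible(x)
}

grid_of <- function(img) {
  if (inherits(img, "image3d"))
    list(dim = dim(img$voxels), spacing = img$spacing, origin = img$origin, d = 3L)
  else if (inherits(img, "slice2d"))
    list(dim = dim(img$pixels), spacing = img$pixel_spacing, origin = img$origin, d = 2L)
  else if (inherits(img, "roi_mask"))
    list(dim = dim(img$mask), spacing = img$spacing, origin = img$origin,
         d = length(dim(img$mask)))
  else stop("expected an image3d, slice2d or roi_mask")
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- grid_of(a); gb <- grid_of(b)
  ga$d == gb$d && identical(ga$dim, gb$dim) &&
    max(abs(ga$spacing - gb$spacing)) <= tol &&
    max(abs(ga$origin - gb$origin)) <= tol
}

image_values <- function(img) {
  if (inherits(img, "image3d")) img$voxels
  else if (inherits(img, "slice2d")) img$pixels
  else if (inherits(img, "roi_mask")) img$mask
  else stop("expected an image3d, slice2d or roi_mask")
}

#' Binary region-of-interest mask on an image grid
#'
#' The mask is congruent with the grid of `grid` (an [image3d()] or
#' [slice2d()]), whose spacing and origin it copies, so voxel counts
#' convert to physical volumes.
#'
#' @param mask Logical (or 0/1) array of the same shape as the grid.
#' @param grid The `image3d`/`slice2d` whose grid the mask lives on, or a
#'   `roi_mask` to copy the grid from.
#' @export
roi_mask <- function(mask, grid) {
  g <- grid_of(grid)
  mask <- as.array(mask)
  if (!identical(dim(mask), as.integer(g$dim)) &&
      !identical(dim(mask), g$dim))
    stop("mask shape does not match the reference grid")
  v <- as.vector(mask)
  if (!all(v %in% c(0, 1, TRUE, FALSE)))
    stop("mask values must be binary (0/1)")
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, spacing = g$spacing, origin = g$origin),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> dims %s  %d foreground voxels (%.3f mm^%d)\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask),
              mask_volume(x), length(dim(x$mask))))
  invisible(x)
}

#' Physical volume (3D, mm^3) or area (2D, mm^2) of a mask
#' @param m A `roi_mask`.
#' @export
mask_volume <- function(m) {
  stopifnot(inherits(m, "roi_mask"))
  sum(m$mask) * prod(m$spacing)
}

#' Physical coordinates of mask foreground voxels (centres, mm)
#' @param m A `roi_mask`.
#' @return An n x d matrix of coordinates.
#' @export
mask_coords <- function(m) {
  stopifnot(inherits(m, "roi_mask"))
  idx <- which(m$mask, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, m$spacing, `*`), 2, m$origin, `+`)
}

#' Ordered, labelled physical-coordinate landmarks
#'
#' A set of named points in one image's physical space (mm), e.g. the
#' six-point brain-edge template used for per-slice fluorescence
#' registration. Two sets are paired when their labels match one-to-one.
#'
#' @param label Character vector of unique labels.
#' @param coords n x 2 or n x 3 matrix of physical coordinates (mm).
#' @param space Identifier of the image space the coordinates live in.
#' @return A data frame of class `landmark_set` with columns `label`,
#'   `x`, `y` (and `z` in 3D), and a `space` attribute.
#' @export
landmark_set <- function(label, coords, space = "unknown") {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || !(ncol(coords) %in% c(2L, 3L)))
    stop("coords must be an n x 2 or n x 3 numeric matrix")
  label <- as.character(label)
  if (length(label) != nrow(coords)) stop("one label per point required")
  if (anyDuplicated(label))
    stop("duplicate landmark labels: ",
         paste(unique(label[duplicated(label)]), collapse = ", "))
  df <- data.frame(label = label, x = coords[, 1], y = coords[, 2],
                   stringsAsFactors = FALSE)
  if (ncol(coords) == 3L) df$z <- coords[, 3]
  structure(df, space = space, class = c("landmark_set", "data.frame"))
}

#' Coordinate matrix of a landmark set
#' @param ls A `landmark_set`.
#' @export
landmark_coords <- function(ls) {
  stopifnot(inherits(ls, "landmark_set"))
  cols <- intersect(c("x", "y", "z"), names(ls))
  as.matrix(as.data.frame(ls)[, cols, drop = FALSE])
}

# Reorder b's rows to pair with a by label; error on any mismatch.
pair_landmarks <- function(a, b) {
  stopifnot(inherits(a, "landmark_set"), inherits(b, "landmark_set"))
  missing_in_b <- setdiff(a$label, b$label)
  missing_in_a <- setdiff(b$label, a$label)
  if (length(missing_in_b) || length(missing_in_a))
    stop("landmark sets are not paired; unmatched labels: ",
         paste(c(missing_in_b, missing_in_a), collapse = ", "))
  b[match(a$label, b$label), , drop = FALSE]
}

# Sample an image at arbitrary physical points (mm). Vectorised
# bi/trilinear or nearest-neighbour pull-back; points outside the grid
# extent get `background`. This is the kernel under resample() and the
# MI objective.
sample_points <- function(img, pts, interp = c("linear", "nearest"),
                          background = 0) {
  interp <- match.arg(interp)
  g <- grid_of(img)
  vals <- image_values(img)
  storage.mode(vals) <- "double"
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
  if (ncol(pts) != g$d) stop("point dimension does not match image")
  # continuous 0-based index
  u <- sweep(sweep(pts, 2, g$origin, `-`), 2, g$spacing, `/`)
  n <- nrow(u)
  out <- rep(as.numeric(background), n)
  if (interp == "nearest") {
    idx <- round(u)
    ok <- rep(TRUE, n)
    for (a in seq_len(g$d)) ok <- ok & idx[, a] >= 0 & idx[, a] <= g$dim[a] - 1L
    if (any(ok)) {
      lin <- idx[ok, 1] + 1
      mult <- 1
      for (a in seq_len(g$d - 1L)) {
        mult <- mult * g$dim[a]
        lin <- lin + idx[ok, a + 1L] * mult
      }
      out[ok] <- vals[lin]
    }
    return(out)
  }
  i0 <- floor(u)
  f <- u - i0
  ok <- rep(TRUE, n)
  for (a in seq_len(g$d)) ok <- ok & u[, a] >= 0 & u[, a] <= g$dim[a] - 1L
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  f <- f[ok, , drop = FALSE]
  # clamp the upper corner so points exactly on the far face stay valid
  i1 <- i0
  for (a in seq_len(g$d)) {
    i0[, a] <- pmin(pmax(i0[, a], 0), g$dim[a] - 1L)
    i1[, a] <- pmin(i0[, a] + 1L, g$dim[a] - 1L)
  }
  lin_index <- function(idx) {
    lin <- idx[, 1] + 1
    mult <- 1
    for (a in seq_len(g$d - 1L)) {
      mult <- mult * g$dim[a]
      lin <- lin + idx[, a + 1L] * mult
    }
    lin
  }
  acc <- 0
  corners <- expand.grid(rep(list(0:1), g$d))
  for (r in seq_len(nrow(corners))) {
    sel <- as.integer(corners[r, ])
    idx <- i0
    w <- rep(1, nrow(i0))
    for (a in seq_len(g$d)) {
      if (sel[a] == 1L) {
        idx[, a] <- i1[, a]
        w <- w * f[, a]
      } else {
        w <- w * (1 - f[, a])
      }
    }
    acc <- acc + w * vals[lin_index(idx)]
  }
  out[ok] <- acc
  out
}

#' Resample an image through a transform onto a target grid
#'
#' Pull-back resampling: for each target voxel centre `x`, the output
#' value is `moving` sampled at `t(x)`, so `t` must map the target
#' physical space into the moving image's physical space (for a forward
#' transform `A` taking moving to target space, pass `invert(A)`).
#' Voxels mapping outside the moving extent are filled with
#' `background`; no extrapolation. Use `interp = "nearest"` for masks
#' and labels, `"linear"` for intensities (e.g. upsampling 0.25/0.5 mm
#' MRI onto the 34.4 um fluorescence grid before surface-distance
#' comparison).
#'
#' @param moving An `image3d`, `slice2d` or `roi_mask` to sample from.
#' @param t `affine_transform` mapping target physical space to moving
#'   physical space.
#' @param target An object carrying the output grid (`image3d`,
#'   `slice2d` or `roi_mask` of matching dimension).
#' @param interp `"linear"` or `"nearest"`.
#' @param background Fill value outside the moving extent (default 0).
#' @return An object on the target grid, of the same class as `moving`
#'   (a `roi_mask` input returns a `roi_mask`; `interp` is forced to
#'   nearest for masks).
#' @export
resample <- function(moving, t, target, interp = c("linear", "nearest"),
                     background = 0) {
  interp <- match.arg(interp)
  stopifnot(inherits(t, "affine_transform"))
  g <- grid_of(target)
  if (transform_dim(t) != g$d || grid_of(moving)$d != g$d)
    stop("transform / image dimensions do not match")
  is_mask <- inherits(moving, "roi_mask")
  if (is_mask) interp <- "nearest"
  ax <- lapply(seq_len(g$d), function(a) g$origin[a] + (seq_len(g$dim[a]) - 1) * g$spacing[a])
  pts <- as.matrix(expand.grid(ax, KEEP.OUT.ATTRS = FALSE))
  vals <- sample_points(moving, apply_transform(t, pts), interp = interp,
                        background = if (is_mask) 0 else background)
  arr <- array(vals, dim = g$dim)
  if (is_mask) {
    tgt <- if (inherits(target, "roi_mask")) {
      structure(list(mask = arr > 0.5, spacing = g$spacing, origin = g$origin),
                class = "roi_mask")
    } else roi_mask(arr > 0.5, target)
    return(tgt)
  }
  if (g$d == 3L) {
    image3d(arr, spacing = g$spacing, origin = g$origin,
            modality = moving$modality)
  } else {
    sl <- if (inherits(target, "slice2d")) target else moving
    slice2d(arr, pixel_spacing = g$spacing,
            slab_thickness = sl$slab_thickness, slab_index = sl$slab_index,
            origin = g$origin, modality = moving$modality)
  }
}

# Separable Gaussian blur of a 2D/3D array, sigma per axis in voxels.
# Truncated at 3 sigma; constant (edge-replicate) padding.
gaussian_blur <- function(arr, sigma) {
  d <- length(dim(arr))
  sigma <- rep(sigma, length.out = d)
  for (a in seq_len(d)) {
    if (sigma[a] <= 0) next
    r <- max(1L, ceiling(3 * sigma[a]))
    k <- exp(-0.5 * ((-r):r / sigma[a])^2)
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, a)
  }
  arr
}

convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  nd <- length(d)
  perm <- c(axis, seq_len(nd)[-axis])
  x <- aperm(arr, perm)
  m <- matrix(x, nrow = d[axis])
  r <- (length(kernel) - 1L) / 2L
  n <- nrow(m)
  pad_top <- m[rep(1L, r), , drop = FALSE]
  pad_bot <- m[rep(n, r), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (i in seq_along(kernel))
    out <- out + kernel[i] * mp[i:(i + n - 1L), , drop = FALSE]
  y <- array(out, dim = d[perm])
  aperm(y, order(perm))
}
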