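#' Read a NIfTI-1 volume into an image3d
#'
#' Spacing is taken from the header `pixdim` (mm). The stored xform is
#' reduced to the package's axis-aligned internal convention: a diagonal
#' xform with negative entries has the corresponding axes flipped so
#' that spacing is positive and the origin names the centre of voxel
#' (1,1,1); an oblique (non-diagonal) xform is rejected — resample such
#' acquisitions to an axis-aligned grid upstream.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param modality Optional modality tag for the result.
#' @return An [image3d()].
#' @export
read_volume <- function(path, modality = "") {
  nim <- RNifti::readNifti(path)
  arr <- as.array(nim)
  attributes(arr) <- list(dim = dim(arr))  # drop niftiImage metadata
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume in ", path)
  pd <- attr(nim, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(nim)
  pd <- pd[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("NIfTI header of ", path,
         " has missing or non-positive pixdim; cannot establish voxel spacing")
  xf <- try(RNifti::xform(nim), silent = TRUE)
  origin <- c(0, 0, 0)
  if (!inherits(xf, "try-error") && is.matrix(xf) && all(dim(xf) == c(4L, 4L))) {
    L <- xf[1:3, 1:3]
    offdiag <- L; diag(offdiag) <- 0
    if (max(abs(offdiag)) > 1e-4 * max(abs(diag(L)), 1))
      stop("oblique acquisition grid in ", path,
           "; resample to an axis-aligned grid before loading")
    origin <- xf[1:3, 4]
    for (a in 1:3) {
      if (diag(L)[a] < 0) {  # flip axis to keep spacing positive
        arr <- flip_axis(arr, a)
        origin[a] <- origin[a] + diag(L)[a] * (dim(arr)[a] - 1L)
      }
    }
  }
  image3d(arr, spacing = pd, origin = origin, modality = modality)
}

flip_axis <- function(arr, axis) {
  idx <- rep(list(quote(expr = )), 3L)
  idx[[axis]] <- rev(seq_len(dim(arr)[axis]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Write an image3d as NIfTI-1
#'
#' Voxels are stored as float32; spacing goes to `pixdim` and the origin
#' to a diagonal sform, so [read_volume()] round-trips voxels bit-exactly
#' (at float32 precision) and spacing to 1e-6.
#'
#' @param img An [image3d()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "image3d"))
  arr <- img$voxels
  storage.mode(arr) <- "double"
  nim <- RNifti::asNifti(structure(arr, pixdim = img$spacing),
                         datatype = "float")
  xf <- diag(4)
  diag(xf)[1:3] <- img$spacing
  xf[1:3, 4] <- img$origin
  RNifti::sform(nim) <- structure(xf, code = 2L)
  RNifti::qform(nim) <- structure(xf, code = 2L)
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' Read a 2D fluorescence/slice image (TIFF or PNG)
#'
#' Physical metadata is not trusted from TIFF tags: pixel spacing and
#' slab thickness are supplied by the caller, defaulting to the IVIS
#' bin-1 pixel (34.4 um) and the 1-mm slice-block pitch. 16-bit integer
#' images are returned on their native integer scale; float TIFFs are
#' returned as stored. Multi-channel images require `channel`.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_spacing Pixel size in mm (scalar or length 2).
#' @param slab_thickness Slab thickness in mm.
#' @param slab_index 0-based slab position in the slice block.
#' @param channel Channel to extract from a multi-channel image (1-based);
#'   required when the file has more than one channel.
#' @param modality Optional tag.
#' @return A [slice2d()]. Pixel rows of the file map to the y axis; the
#'   returned matrix is indexed `[x, y]` per the package convention.
#' @export
read_slice <- function(path, pixel_spacing = 0.0344, slab_thickness = 1,
                       slab_index = 0L, channel = NULL, modality = "") {
  is_png <- grepl("\\.png$", path, ignore.case = TRUE)
  if (is_png) {
    m <- png::readPNG(path, info = TRUE)
    depth <- attr(m, "info")$bit.depth %||% 8
    scale <- 2^depth - 1
  } else {
    m <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(m, "bits.per.sample") %||% 8L
    # 32-bit TIFF samples are floats stored as-is; integer depths come
    # back rescaled to [0, 1] and are restored to their native scale
    scale <- if (bits >= 32L) 1 else 2^bits - 1
  }
  if (length(dim(m)) == 3L) {
    if (is.null(channel))
      stop("multi-channel image (", dim(m)[3],
           " channels); pass `channel` to select one")
    m <- m[, , channel]
  }
  if (scale > 1) {
    m <- round(m * scale)
    storage.mode(m) <- "integer"
  }
  attributes(m) <- list(dim = dim(m))
  slice2d(t(m), pixel_spacing = pixel_spacing, slab_thickness = slab_thickness,
          slab_index = slab_index, modality = modality)
}

#' Write a slice2d as TIFF (16-bit integer or 32-bit float) or PNG
#'
#' Integer-valued slices in [0, 65535] are written as 16-bit TIFF
#' (lossless). Other values are written as 32-bit float TIFF, which
#' stores the [0, 1] range losslessly at float32 precision — the
#' natural domain for normalised fluorescence signal; values outside
#' it are rejected (rescale, or quantise to 16-bit counts as
#' [write_study()] does). PNG output is 8-bit and requires integers in
#' [0, 255].
#'
#' @param slice A [slice2d()].
#' @param path Output path; format chosen by extension.
#' @export
write_slice <- function(slice, path) {
  stopifnot(inherits(slice, "slice2d"))
  m <- t(slice$pixels)
  is_png <- grepl("\\.png$", path, ignore.case = TRUE)
  integral <- all(m == round(m)) && min(m) >= 0 && max(m) <= 65535
  if (is_png) {
    if (!(all(m == round(m)) && min(m) >= 0 && max(m) <= 255))
      stop("PNG output requires integer pixel values in [0, 255]")
    png::writePNG(m / 255, path)
  } else if (integral) {
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  } else {
    if (min(m) < 0 || max(m) > 1)
      stop("float TIFF output stores the [0, 1] range; rescale the slice ",
           "or quantise it to integer counts first")
    storage.mode(m) <- "double"
    tiff::writeTIFF(m, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read landmarks from CSV
#'
#' Accepts the package's minimal dialect — a header `label,x,y[,z]` with
#' coordinates in mm — and, as a convenience, 3D Slicer FCSV fiducial
#' exports whose data lines begin `vtkMRMLMarkupsFiducialNode`.
#'
#' @param path CSV (or FCSV) file path.
#' @param space Space label to attach.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, space = "unknown") {
  first <- readLines(path, n = 30L)
  if (any(grepl("^vtkMRMLMarkupsFiducialNode", first)))
    return(read_landmarks_fcsv(path, space))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("label", "x", "y")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns label,x,y[,z]")
  cols <- intersect(c("x", "y", "z"), names(df))
  co <- matrix(NA_real_, nrow(df), length(cols))
  for (j in seq_along(cols)) {
    v <- suppressWarnings(as.numeric(df[[cols[j]]]))
    bad <- which(is.na(v) & !is.na(df[[cols[j]]]))
    if (length(bad))
      stop(sprintf("non-numeric %s coordinate in row %d of %s",
                   cols[j], bad[1], path))
    co[, j] <- v
  }
  landmark_set(df$label, co, space = space)
}

read_landmarks_fcsv <- function(path, space = "unknown") {
  lines <- grep("^vtkMRMLMarkupsFiducialNode", readLines(path), value = TRUE)
  if (!length(lines)) stop("no fiducial lines in ", path)
  parts <- strsplit(lines, ",")
  co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  lab <- vapply(parts, function(p) if (length(p) >= 12) p[12] else p[1],
                character(1))
  landmark_set(lab, co, space = space)
}

#' Write landmarks as CSV (`label,x,y[,z]`, mm)
#' @param ls A [landmark_set()].
#' @param path Output path.
#' @export
write_landmarks <- function(ls, path) {
  stopifnot(inherits(ls, "landmark_set"))
  df <- as.data.frame(ls)
  for (cl in intersect(c("x", "y", "z"), names(df)))
    df[[cl]] <- sprintf("%.12g", df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write transforms as plain text
#'
#' The format is two header lines (`kind:` and `dim:`) followed by the
#' row-major homogeneous matrix, full precision, so round trips are
#' exact to 1e-12. A matrix whose claimed kind fails validation is
#' demoted to `affine` with a warning; a singular matrix is rejected.
#'
#' @param path File path.
#' @return An [affine_transform()].
#' @export
read_transform <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kind_line <- grep("^kind:", lines, value = TRUE)
  if (!length(kind_line)) stop("malformed transform file (missing kind): ", path)
  kind <- trimws(sub("^kind:", "", kind_line[1]))
  rows <- lines[!grepl("^(kind|dim):", lines)]
  m <- t(vapply(strsplit(rows, "[ \t]+"),
                function(p) as.numeric(p), numeric(length(strsplit(rows[1], "[ \t]+")[[1]]))))
  if (any(!is.finite(m)) || nrow(m) != ncol(m) || !(nrow(m) %in% c(3L, 4L)))
    stop("malformed transform matrix in ", path)
  tr <- try(affine_transform(m, kind = kind), silent = TRUE)
  if (inherits(tr, "try-error")) {
    tr2 <- try(affine_transform(m, kind = "affine"), silent = TRUE)
    if (inherits(tr2, "try-error"))
      stop("transform in ", path, " is not invertible")
    warning("matrix in ", path, " does not satisfy kind '", kind,
            "'; demoted to affine")
    return(tr2)
  }
  tr
}

#' @rdname read_transform
#' @param t An [affine_transform()] to write.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "affine_transform"))
  n <- nrow(t$matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("kind: ", t$kind), paste0("dim: ", n - 1L)), con)
  for (r in seq_len(n))
    writeLines(paste(sprintf("%.17g", t$matrix[r, ]), collapse = " "), con)
  invisible(path)
}

#' Load a study layout from YAML
#'
#' A study layout names the files of one co-registration study: the
#' in-vivo MRI, PET and ex-vivo MRI volumes, the ordered per-slab
#' fluorescence images, and any landmark and mask files, plus per-image
#' spacing overrides. Paths are resolved relative to the YAML file.
#' Every referenced file must exist; fluorescence slab indices must be
#' contiguous from 0.
#'
#' @param path Path to the layout YAML.
#' @return A list of class `study_layout` with absolute paths.
#' @export
read_study_layout <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    p2 <- ifelse(grepl("^/", p), p, file.path(base, p))
    missing <- p2[!file.exists(p2)]
    if (length(missing))
      stop("study layout references missing file(s): ",
           paste(missing, collapse = ", "))
    p2
  }
  lay <- list(
    invivo_mri = resolve(cfg$invivo_mri),
    pet = resolve(cfg$pet),
    exvivo_mri = resolve(cfg$exvivo_mri),
    fluor_slabs = resolve(unlist(cfg$fluor_slabs)),
    landmarks = lapply(cfg$landmarks, resolve),
    masks = lapply(cfg$masks, resolve),
    spacing = cfg$spacing,
    fluor_pixel_spacing = cfg$fluor_pixel_spacing %||% 0.0344,
    slab_pitch = cfg$slab_pitch %||% 1.0,
    slab_face0 = cfg$slab_face0
  )
  if (!is.null(cfg$fluor_slab_index)) {
    idx <- as.integer(unlist(cfg$fluor_slab_index))
    if (!identical(sort(idx), seq_along(idx) - 1L))
      stop("fluorescence slab indices must be contiguous from 0")
    lay$fluor_slab_index <- idx
  } else if (length(lay$fluor_slabs)) {
    lay$fluor_slab_index <- seq_along(lay$fluor_slabs) - 1L
  }
  structure(lay, class = "study_layout")
}
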