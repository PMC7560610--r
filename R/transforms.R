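#' Affine transforms in physical (mm) space
#'
#' An `affine_transform` stores a homogeneous matrix acting on physical
#' coordinates in millimetres: 3x3 for 2D, 4x4 for 3D. The `kind` field
#' records the strongest structure the matrix is claimed to have:
#' `"rigid"` (rotation + translation), `"similarity"` (rigid plus one
#' uniform scale factor), or `"affine"` (any invertible linear part, 12
#' free parameters in 3D). Transforms always act in physical space, never
#' voxel-index space, so images with different grids (0.25 mm MRI, 0.5 mm
#' PET, 34.4 um fluorescence) compose without bookkeeping.
#'
#' @param matrix Homogeneous matrix, (d+1) x (d+1) with last row (0,...,0,1).
#' @param kind One of `"rigid"`, `"similarity"`, `"affine"`.
#' @param tol Tolerance used to verify the structural claim in `kind`.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix, kind = c("affine", "rigid", "similarity"),
                             tol = 1e-6) {
  kind <- match.arg(kind)
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  if (!is.numeric(matrix) || n != ncol(matrix) || !(n %in% c(3L, 4L)))
    stop("transform matrix must be a numeric 3x3 (2D) or 4x4 (3D) matrix")
  if (max(abs(matrix[n, ] - c(rep(0, n - 1L), 1))) > tol)
    stop("last row of a homogeneous matrix must be (0, ..., 0, 1)")
  matrix[n, ] <- c(rep(0, n - 1L), 1)
  d <- n - 1L
  L <- matrix[seq_len(d), seq_len(d), drop = FALSE]
  dt <- det(L)
  if (abs(dt) < 1e-12)
    stop("linear part is singular; transform is not invertible")
  if (kind == "rigid") {
    if (max(abs(crossprod(L) - diag(d))) > tol || dt < 0)
      stop("kind = 'rigid' requires an orthonormal linear part with det +1")
  } else if (kind == "similarity") {
    s <- dt^(1 / d)
    if (!(dt > 0) || max(abs(crossprod(L / s) - diag(d))) > tol)
      stop("kind = 'similarity' requires linear part s*R with s > 0, det(R) = +1")
  }
  structure(list(matrix = matrix, kind = kind), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform> %dD, kind = %s\n", transform_dim(x), x$kind))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Spatial dimension (2 or 3) of a transform
#' @param t An `affine_transform`.
#' @export
transform_dim <- function(t) nrow(t$matrix) - 1L

#' Identity transform
#' @param d Spatial dimension, 2 or 3.
#' @export
identity_transform <- function(d = 3L) {
  affine_transform(diag(d + 1L), kind = "rigid")
}

#' Pure translation
#' @param shift Numeric length-2 or length-3 offset in mm.
#' @export
translation_transform <- function(shift) {
  d <- length(shift)
  m <- diag(d + 1L)
  m[seq_len(d), d + 1L] <- shift
  affine_transform(m, kind = "rigid")
}

# Rotation matrix about x, y, z Euler angles (radians), applied as Rz Ry Rx.
rotation_matrix_3d <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Rigid transform from rotation angles, translation and rotation centre
#'
#' 3D: `angles` are Euler angles (radians) about x, y, z applied as
#' Rz Ry Rx. 2D: a single angle. The rotation is taken about `center`
#' (mm), then `shift` is added: x -> R (x - c) + c + t.
#'
#' @param angles Rotation angle(s) in radians (length 3 in 3D, 1 in 2D).
#' @param shift Translation in mm (defaults to zero).
#' @param center Rotation centre in mm (defaults to the origin).
#' @export
rigid_transform <- function(angles, shift = NULL, center = NULL) {
  if (length(angles) == 3L) {
    R <- rotation_matrix_3d(angles); d <- 3L
  } else if (length(angles) == 1L) {
    R <- rbind(c(cos(angles), -sin(angles)), c(sin(angles), cos(angles)))
    d <- 2L
  } else stop("angles must have length 1 (2D) or 3 (3D)")
  if (is.null(shift)) shift <- rep(0, d)
  if (is.null(center)) center <- rep(0, d)
  m <- diag(d + 1L)
  m[seq_len(d), seq_len(d)] <- R
  m[seq_len(d), d + 1L] <- center - R %*% center + shift
  affine_transform(m, kind = "rigid")
}

#' 2D similarity transform from scale, angle and translation
#'
#' x -> s R(theta) (x - c) + c + t, with `s > 0` and `theta` in radians.
#'
#' @param s Uniform scale factor (> 0).
#' @param theta Rotation angle in radians.
#' @param shift Length-2 translation in mm.
#' @param center Length-2 rotation/scaling centre in mm.
#' @export
similarity_transform_2d <- function(s, theta = 0, shift = c(0, 0),
                                    center = c(0, 0)) {
  stopifnot(s > 0)
  R <- s * rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  m <- diag(3)
  m[1:2, 1:2] <- R
  m[1:2, 3] <- center - R %*% center + shift
  affine_transform(m, kind = "similarity")
}

#' Uniform (or per-axis) scaling about a centre
#' @param s Scale factor(s); a scalar gives a similarity, a vector of
#'   per-axis factors a general affine.
#' @param d Spatial dimension (ignored when `s` has length `d`).
#' @param center Fixed point of the scaling, in mm.
#' @export
scaling_transform <- function(s, d = 3L, center = NULL) {
  if (length(s) > 1L) d <- length(s)
  sv <- rep(s, length.out = d)
  if (any(sv <= 0)) stop("scale factors must be positive")
  if (is.null(center)) center <- rep(0, d)
  m <- diag(d + 1L)
  diag(m)[seq_len(d)] <- sv
  m[seq_len(d), d + 1L] <- center * (1 - sv)
  affine_transform(m, kind = if (length(unique(sv)) == 1L && length(s) == 1L)
    "similarity" else "affine")
}

.kind_rank <- c(rigid = 1L, similarity = 2L, affine = 3L)

#' Compose two transforms
#'
#' `compose(A, B)` is the transform mapping `x` to `A(B(x))`; the same
#' chaining the registration pipeline uses when the in-vivo-to-ex-vivo
#' affine is applied on top of the PET-to-MRI rigid result. The kind of
#' the composite is the weakest of the two (rigid o rigid = rigid,
#' anything o affine = affine).
#'
#' @param outer,inner `affine_transform`s of matching dimension.
#' @export
compose <- function(outer, inner) {
  stopifnot(inherits(outer, "affine_transform"),
            inherits(inner, "affine_transform"))
  if (transform_dim(outer) != transform_dim(inner))
    stop("cannot compose transforms of different spatial dimension")
  kinds <- c(outer$kind, inner$kind)
  affine_transform(outer$matrix %*% inner$matrix,
                   kind = names(which.max(.kind_rank[kinds])))
}

#' Invert a transform
#' @param t An `affine_transform` with invertible linear part.
#' @export
invert <- function(t) {
  stopifnot(inherits(t, "affine_transform"))
  affine_transform(solve(t$matrix), kind = t$kind)
}

#' Apply a transform to points or landmarks
#'
#' @param t An `affine_transform`.
#' @param x An n x d matrix of physical coordinates (mm), a length-d
#'   vector, or a [landmark_set()].
#' @param space For landmark sets, the space label of the result.
#' @return Transformed coordinates of the same shape; for landmark sets,
#'   a landmark set with labels and order preserved.
#' @export
apply_transform <- function(t, x, space = NULL) {
  stopifnot(inherits(t, "affine_transform"))
  d <- transform_dim(t)
  if (inherits(x, "landmark_set")) {
    pts <- apply_transform(t, landmark_coords(x))
    return(landmark_set(x$label, pts,
                        space = space %||% paste0(attr(x, "space"), "+t")))
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != d)
    stop(sprintf("points are %dD but transform is %dD", ncol(x), d))
  out <- cbind(x, 1) %*% t(t$matrix)
  out[, seq_len(d), drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decompose the linear part of a transform
#'
#' Returns the singular values of the linear part (the per-axis scale
#' factors for a pure scaling/similarity), its determinant, and the
#' translation. Used to report recovered shrinkage factors.
#'
#' @param t An `affine_transform`.
#' @return A list with `scales` (singular values, sorted decreasing),
#'   `det`, and `translation`.
#' @export
transform_params <- function(t) {
  d <- transform_dim(t)
  L <- t$matrix[seq_len(d), seq_len(d), drop = FALSE]
  list(scales = svd(L)$d, det = det(L), translation = t$matrix[seq_len(d), d + 1L])
}

#' Rotation angle of a rigid or similarity transform
#'
#' For 2D, the signed angle in radians; for 3D, the total rotation angle
#' of the orthonormal factor (from its trace), in radians.
#'
#' @param t An `affine_transform` whose linear part is s*R.
#' @export
rotation_angle <- function(t) {
  d <- transform_dim(t)
  L <- t$matrix[seq_len(d), seq_len(d), drop = FALSE]
  R <- L / det(L)^(1 / d)
  if (d == 2L) atan2(R[2, 1], R[1, 1])
  else acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
}
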