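#' Rigid-body transform
#'
#' A proper rigid-body motion: a 3x3 rotation matrix plus a translation
#' vector, applied to ligand coordinates about an explicit pivot (see
#' [apply_transform()]). Ligand poses are manipulated purely in Cartesian
#' space: a move is a direct rotation/translation of the coordinate list,
#' with no internal-coordinate machinery.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Numeric 3-vector, Angstrom.
#' @return An object of class `rigid_transform`.
#' @examples
#' rigid_transform(diag(3), c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  check_rotation(rotation)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

check_rotation <- function(R, tol = 1e-9) {
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > tol * 1e3) {
    stop("rotation matrix is not orthonormal with determinant +1", call. = FALSE)
  }
  invisible(R)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", sprintf("%.4f", x$translation), "\n")
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` is the transform equivalent to applying `b`
#' first, then `a` (both about the same pivot).
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Apply a rigid transform to coordinates about a pivot
#'
#' Computes `R (x - pivot) + pivot + t` for every row of `coords`. Pairwise
#' distances are preserved to numerical precision, so ligand internal
#' geometry is untouched by any move expressed this way.
#'
#' @param coords n x 3 numeric matrix of coordinates, Angstrom.
#' @param transform A [rigid_transform()].
#' @param pivot Numeric 3-vector; the rotation center. Ligand moves in this
#'   package pivot about the heavy-atom centroid.
#' @return n x 3 matrix of transformed coordinates.
#' @examples
#' sq <- matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE)
#' apply_transform(sq, rigid_transform(diag(3), c(0, 0, 1)), c(0, 0, 0))
#' @export
apply_transform <- function(coords, transform, pivot) {
  stopifnot(inherits(transform, "rigid_transform"), length(pivot) == 3)
  coords <- as.matrix(coords)
  shift <- pivot + transform$translation
  out <- sweep(coords, 2, pivot) %*% t(transform$rotation)
  sweep(out, 2, shift, "+")
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula. The axis is normalised internally.
#'
#' @param axis Numeric 3-vector (need not be unit length).
#' @param angle_deg Rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Draw a uniformly random rotation
#'
#' Samples SO(3) uniformly via the random-quaternion method (four iid
#' standard normals, normalised). Uses the global R RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' @return A [rigid_transform()] with zero translation.
#' @export
random_uniform_rotation <- function() {
  rigid_transform(rand_rotation_matrix(), c(0, 0, 0))
}

#' Draw a small random rigid perturbation
#'
#' Translation uniform in the ball of radius `max_trans`; rotation about a
#' uniformly random axis by an angle uniform in `[0, max_angle]`. With both
#' maxima zero this returns the identity transform exactly.
#'
#' @param max_trans Maximum translation magnitude, Angstrom (>= 0).
#' @param max_angle Maximum rotation angle, degrees, in `[0, 360]`.
#' @return A [rigid_transform()].
#' @export
random_small_perturbation <- function(max_trans, max_angle) {
  stopifnot(max_trans >= 0, max_angle >= 0, max_angle <= 360)
  pert <- rand_perturbation(max_trans, max_angle)
  rigid_transform(pert$R, pert$t)
}

#' Heavy-atom RMSD between two coordinate sets, no superposition
#'
#' Root-mean-square deviation over paired rows in a fixed frame (the
#' receptor frame): the two sets must have the same atoms in the same order,
#' and no alignment is performed. This is the pose-accuracy measure used
#' throughout; poses within 2.0 A of the native placement count as correct.
#' No symmetry correction is applied (identity atom mapping only).
#'
#' @param a,b n x 3 coordinate matrices with identical atom ordering.
#' @return RMSD in Angstrom (scalar >= 0).
#' @examples
#' a <- matrix(rnorm(9), 3, 3)
#' ligand_rmsd(a, a + 2)  # sqrt(3 * 2^2) = 3.46
#' @export
ligand_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) {
    stop("coordinate sets differ in size: ", nrow(a), " vs ", nrow(b),
         " atoms", call. = FALSE)
  }
  sqrt(sum((a - b)^2) / nrow(a))
}

centroid <- function(coords) colMeans(as.matrix(coords))

# ---- internal fast paths (no class construction, no validation) ----

# add a 3-vector to every row without sweep()'s aperm overhead
row_shift <- function(m, v) {
  m[, 1] <- m[, 1] + v[1]
  m[, 2] <- m[, 2] + v[2]
  m[, 3] <- m[, 3] + v[3]
  m
}

# rotate rows of m about pivot by rotation matrix R, then translate by t
rigid_move <- function(m, R, t, pivot) {
  out <- row_shift(m, -pivot) %*% t.default(R)
  row_shift(out, pivot + t)
}

# raw uniform random rotation matrix (quaternion method)
rand_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z),  2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2),  2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x),  1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# raw small perturbation: list(R, t)
rand_perturbation <- function(max_trans, max_angle) {
  t <- if (max_trans > 0) {
    d <- stats::rnorm(3)
    d / sqrt(sum(d^2)) * max_trans * stats::runif(1)^(1 / 3)
  } else c(0, 0, 0)
  R <- if (max_angle > 0) {
    rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, max_angle))
  } else diag(3)
  list(R = R, t = t)
}
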