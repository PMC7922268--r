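# 3D/2D geometric primitives: planes, signed distances, extremal queries,
# Rodrigues rotations, planar projections and algebraic circle fitting.
# Units: millimetres everywhere; angles in degrees at API boundaries.

.unit_tol <- 1e-9

vnorm <- function(v) sqrt(sum(v * v))

#' Normalize a vector to unit length
#'
#' @param v Numeric 3-vector (or any length).
#' @return Unit vector in the direction of `v`.
#' @keywords internal
normalize <- function(v) {
  n <- vnorm(v)
  if (!is.finite(n) || n < 1e-12)
    stop("cannot normalize a (near-)zero or non-finite vector", call. = FALSE)
  v / n
}

check_vec3 <- function(v, what = "vector") {
  if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v)))
    stop(sprintf("%s must be a finite numeric 3-vector", what), call. = FALSE)
  invisible(v)
}

#' Construct an oriented plane
#'
#' A plane is stored as a point and a unit normal; by convention the positive
#' halfspace (positive signed distance) is the resected side of a cut.
#'
#' @param point Numeric 3-vector on the plane (mm).
#' @param normal Numeric 3-vector; normalized internally, must be non-zero.
#' @return An object of class `plane` with elements `point` and `normal`.
#' @export
plane <- function(point, normal) {
  check_vec3(point, "plane point")
  check_vec3(normal, "plane normal")
  structure(list(point = as.numeric(point), normal = normalize(normal)),
            class = "plane")
}

#' Signed distance from a plane
#'
#' Positive on the side the normal points to (the resected side for cut
#' planes).
#'
#' @param pl A [plane()].
#' @param p A numeric 3-vector or an n x 3 matrix of points (mm).
#' @return Scalar or length-n numeric vector of signed distances (mm).
#' @export
signed_distance <- function(pl, p) {
  stopifnot(inherits(pl, "plane"))
  if (is.matrix(p)) {
    if (ncol(p) != 3L || any(!is.finite(p)))
      stop("points must be a finite n x 3 matrix", call. = FALSE)
    drop((p %*% pl$normal) - sum(pl$point * pl$normal))
  } else {
    check_vec3(p, "point")
    sum(pl$normal * (p - pl$point))
  }
}

#' Extremal point of a point set along a direction
#'
#' Returns the point maximizing the dot product with `direction`. Ties are
#' broken by first occurrence in input order (deterministic).
#'
#' @param points An n x 3 numeric matrix (rows are points, mm).
#' @param direction Numeric 3-vector (need not be unit; must be non-zero).
#' @return The extremal point as a numeric 3-vector.
#' @export
extreme_point <- function(points, direction) {
  if (!is.matrix(points) || ncol(points) != 3L || nrow(points) < 1L)
    stop("points must be a non-empty n x 3 matrix", call. = FALSE)
  check_vec3(direction, "direction")
  if (vnorm(direction) < 1e-12) stop("direction must be non-zero", call. = FALSE)
  scores <- drop(points %*% direction)
  as.numeric(points[which.max(scores), ])
}

#' Rotate a vector about an axis (Rodrigues' formula)
#'
#' @param v Numeric 3-vector to rotate.
#' @param axis Unit numeric 3-vector (|axis| = 1 within 1e-6).
#' @param angle_deg Rotation angle in degrees (right-hand rule about `axis`).
#' @return The rotated 3-vector; norm is preserved.
#' @export
rotate_about_axis <- function(v, axis, angle_deg) {
  check_vec3(v, "v"); check_vec3(axis, "axis")
  n <- vnorm(axis)
  if (n < 1e-12) stop("rotation axis must be non-zero", call. = FALSE)
  if (abs(n - 1) > 1e-6) stop("rotation axis must be unit length", call. = FALSE)
  th <- angle_deg * pi / 180
  k <- axis
  v * cos(th) + cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

#' Cross product of two 3-vectors
#' @param a,b Numeric 3-vectors.
#' @return Numeric 3-vector `a x b`.
#' @export
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Algebraic (Kasa) least-squares circle fit in 2D
#'
#' Solves the linear least-squares system of the algebraic circle equation;
#' exact (to solver precision) when the points lie on a circle. Requires at
#' least 3 non-collinear points.
#'
#' @param points An n x 2 numeric matrix (mm).
#' @return An object of class `circle2d`: list with `center` (2-vector, mm)
#'   and `radius` (mm).
#' @export
fit_circle_2d <- function(points) {
  if (!is.matrix(points) || ncol(points) != 2L)
    stop("points must be an n x 2 matrix", call. = FALSE)
  if (nrow(points) < 3L)
    stop("circle fit needs at least 3 points", call. = FALSE)
  if (any(!is.finite(points))) stop("non-finite coordinates", call. = FALSE)
  x <- points[, 1]; y <- points[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  # collinearity: rank of centred coordinates
  cc <- cbind(x - mean(x), y - mean(y))
  sv <- svd(cc, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-8 * max(sv[1], 1))
    stop("degenerate circle fit: points are collinear", call. = FALSE)
  sol <- qr.solve(A, b)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (r2 <= 0) stop("degenerate circle fit: non-positive radius", call. = FALSE)
  structure(list(center = as.numeric(sol[1:2]), radius = sqrt(r2)),
            class = "circle2d")
}

#' Project points into a plane's 2D coordinate system
#'
#' @param p Numeric 3-vector or n x 3 matrix.
#' @param origin Numeric 3-vector, the 2D origin.
#' @param basis A 3 x 2 matrix whose columns are orthonormal in-plane axes.
#' @return 2-vector or n x 2 matrix of in-plane coordinates.
#' @export
project_to_plane <- function(p, origin, basis) {
  check_vec3(origin, "origin")
  if (!is.matrix(basis) || !all(dim(basis) == c(3L, 2L)))
    stop("basis must be a 3 x 2 matrix", call. = FALSE)
  g <- crossprod(basis)
  if (max(abs(g - diag(2))) > 1e-9)
    stop("basis must be orthonormal within 1e-9", call. = FALSE)
  if (is.matrix(p)) {
    sweep(p, 2, origin) %*% basis
  } else {
    check_vec3(p, "point")
    drop((p - origin) %*% basis)
  }
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("plane: point (%.3f, %.3f, %.3f), normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' @export
print.circle2d <- function(x, ...) {
  cat(sprintf("circle2d: center (%.3f, %.3f), radius %.3f mm\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}
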