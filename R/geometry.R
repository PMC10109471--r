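#' @keywords internal
"_PACKAGE"

#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% filter mutate select arrange group_by summarise ungroup
#'   bind_rows left_join distinct across n row_number desc pull rename
#' @importFrom rlang .data abort warn
#' @importFrom stats sd quantile rnorm runif setNames
NULL

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalise a near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Right-handed rotation by `theta` degrees about the direction `axis`
#' (Rodrigues' formula).
#'
#' @param axis Numeric length-3 direction (need not be unit).
#' @param theta Angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, theta) {
  u <- unitv(axis)
  th <- theta * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rot_z <- function(theta) rotation_about(c(0, 0, 1), theta)

#' Signed torsion (dihedral) angle of four points
#'
#' IUPAC convention: the angle between the plane (p1, p2, p3) and the plane
#' (p2, p3, p4), measured about the p2-p3 axis; invariant under reversal of
#' the point order.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinates.
#' @return Angle in degrees in (-180, 180].
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-6 || vnorm(n2) < 1e-6)
    abort("degenerate (colinear) point quadruple: torsion undefined")
  b2u <- unitv(b2)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2u)
  atan2(y, x) * 180 / pi
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation and translation taking `mobile` onto `target`.
#'
#' @param mobile,target n x 3 coordinate matrices with matched rows (n >= 3,
#'   non-colinear).
#' @return A `rigid_transform`: list with `R` (3x3, det +1), `t` (length 3),
#'   and `rmsd` of the superposed selection.
#' @export
kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) abort("selections differ in size")
  if (nrow(mobile) < 3) abort("need at least 3 atoms to superpose")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  if (svd(A)$d[2] < 1e-8) abort("colinear selection: superposition underdetermined")
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- ct - as.numeric(R %*% cm)
  fitted <- sweep(mobile %*% t(R), 2, tr, "+")
  out <- list(R = R, t = tr, rmsd = sqrt(mean(rowSums((fitted - target)^2))))
  class(out) <- "rigid_transform"
  out
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 matrix (or length-3 vector).
#' @param tf A `rigid_transform` from [kabsch()], or a list with `R` and `t`.
#' @return Transformed coordinates, same shape as input.
#' @export
apply_transform <- function(xyz, tf) {
  if (is.null(dim(xyz))) return(as.numeric(tf$R %*% xyz + tf$t))
  sweep(as.matrix(xyz) %*% t(tf$R), 2, tf$t, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rmsd =", signif(x$rmsd, 4), "A\n")
  invisible(x)
}

#' Rotate coordinates about an axis line
#'
#' @param xyz n x 3 coordinate matrix.
#' @param point A point on the axis.
#' @param axis Axis direction (normalised internally).
#' @param theta Rotation angle in degrees (right-handed about `axis`).
#' @return The rotated n x 3 matrix.
#' @export
rotate_about_line <- function(xyz, point, axis, theta) {
  R <- rotation_about(axis, theta)
  sweep(sweep(as.matrix(xyz), 2, point) %*% t(R), 2, point, "+")
}

#' Best-fit plane through points
#'
#' @param xyz n x 3 matrix, n >= 3.
#' @return List with `point` (centroid) and `normal` (unit vector).
#' @export
fit_plane <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3) abort("need >= 3 points for a plane")
  ctr <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, ctr))
  if (s$d[2] < 1e-9) abort("colinear points: plane undefined")
  list(point = ctr, normal = unitv(s$v[, 3]))
}

#' Angle between two vectors
#' @param a,b Numeric length-3 vectors.
#' @return Angle in degrees, in [0, 180].
#' @export
vec_angle <- function(a, b) {
  acos(pmin(1, pmax(-1, sum(unitv(a) * unitv(b))))) * 180 / pi
}

# minimum cross-set distance (with optional per-pair output), done blockwise
cross_dist_min <- function(xa, xb) {
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(max(0, min(d2)))
}

cross_dist_matrix <- function(xa, xb) {
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
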