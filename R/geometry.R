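#' @importFrom stats runif rnorm sd cor setNames
#' @importFrom utils head tail
#' @importFrom rlang .data
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Dihedral angle between four points
#'
#' IUPAC sign convention (right-handed), returned in degrees in \[-180, 180\].
#' Rows of the inputs are points; the angle is measured about the b-c axis.
#' Degenerate (collinear) geometries return a defined value (0) rather than
#' failing, so callers never see NaN.
#'
#' @param a,b,c,d numeric length-3 coordinate vectors (Angstrom).
#' @return dihedral angle in degrees.
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  if (abs(x) < 1e-12 && abs(y) < 1e-12) return(0)  # collinear guard
  -atan2(y, x) * 180 / pi
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Place atom D given positions A, B, C and internal coordinates:
# bond |CD|, angle B-C-D (deg), dihedral A-B-C-D (deg).  NeRF construction.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d2 <- c(bond * cos(pi - ang),
          bond * cos(dih) * sin(pi - ang),
          bond * sin(dih) * sin(pi - ang))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) {
    # collinear reference frame: pick any perpendicular
    n <- pracma_cross(bc, c(1, 0, 0))
    if (sqrt(sum(n^2)) < 1e-6) n <- pracma_cross(bc, c(0, 1, 0))
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- pracma_cross(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(c + rot %*% d2)
}

# Rotation matrix about unit axis u by theta degrees (Rodrigues).
rotation_matrix <- function(axis, theta_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- theta_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Returns the rotation matrix and translation that superpose `mobile` onto
#' `fixed` (both n x 3 matrices of paired points), minimising RMSD.
#'
#' @param fixed,mobile n x 3 coordinate matrices with matched rows.
#' @return list with `R` (3 x 3), `t` (length 3); apply as `x %*% R + t`.
#' @keywords internal
kabsch_fit <- function(fixed, mobile) {
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  A <- sweep(mobile, 2, cm)
  B <- sweep(fixed, 2, cf)
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  list(R = R, t = as.numeric(cf - cm %*% R))
}

rmsd_xyz <- function(x, y) sqrt(mean(rowSums((x - y)^2)))

# Pairwise squared Euclidean distances between rows of a and rows of b.
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0
  d2
}
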