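# Small vector-geometry helpers shared by the helix builder, the sampler and
# the kink descriptors. All angles are degrees unless noted.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vcross <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

vnorm <- function(u) sqrt(sum(u * u))

vunit <- function(u) {
  n <- vnorm(u)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  u / n
}

#' Wrap an angle in degrees to the interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped to (-180, 180].
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Signed angle (degrees) from u to v about `axis`, counterclockwise positive
# by the right-hand rule looking along +axis. u and v need not be unit or
# exactly perpendicular to axis; their components along axis are ignored.
signed_angle_about <- function(u, v, axis) {
  a <- vunit(axis)
  up <- u - sum(u * a) * a
  vp <- v - sum(v * a) * a
  if (vnorm(up) < 1e-12 || vnorm(vp) < 1e-12)
    stop("degenerate vector parallel to the reference axis")
  rad2deg(atan2(sum(a * vcross(up, vp)), sum(up * vp)))
}

# Rotation matrix for a rotation of `theta_deg` about unit axis `axis`
# (Rodrigues formula).
rotation_matrix <- function(axis, theta_deg) {
  a <- vunit(axis)
  th <- deg2rad(theta_deg)
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, -a[3L], a[2L],
                a[3L], 0, -a[1L],
                -a[2L], a[1L], 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * (a %o% a)
}

# Minimal rotation matrix mapping unit vector u onto unit vector v.
rotation_between <- function(u, v) {
  u <- vunit(u); v <- vunit(v)
  w <- vcross(u, v)
  s <- vnorm(w)
  if (s < 1e-12) {
    if (sum(u * v) > 0) return(diag(3L))
    # antiparallel: rotate 180 degrees about any perpendicular
    p <- vcross(u, if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
    return(rotation_matrix(p, 180))
  }
  rotation_matrix(w, rad2deg(atan2(s, sum(u * v))))
}

# Kabsch superposition: rotation R and translation t minimising
# || (x %*% R + t) - y ||^2 over rows. x, y are n x 3 matrices of paired
# points. Returns list(R, t) to be applied as x %*% R + rep(t, each = n).
kabsch <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3L, ncol(y) == 3L)
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2L, cx); y0 <- sweep(y, 2L, cy)
  s <- svd(crossprod(x0, y0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, t = cy - as.numeric(cx %*% R))
}

apply_kabsch <- function(x, fit) {
  sweep(x %*% fit$R, 2L, fit$t, "+")
}

# All pairwise distances between the rows of two n x 3 matrices.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
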