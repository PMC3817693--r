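# Internal-coordinate geometry helpers (R side; used for chain building,
# CCD and superposition -- the per-call cost is small, hot loops live in C++).

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) a / vnorm(a)

# dihedral angle a-b-c-d in degrees, range (-180, 180]
dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m <- vcross(n1, vunit(b2))
  ang <- atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

angle_deg <- function(a, b, c) {
  u <- vunit(a - b); v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# NeRF placement: returns the point d with |c-d| = bond, angle(b,c,d) =
# theta (degrees) and dihedral(a,b,c,d) = chi (degrees)
place_atom <- function(a, b, c, bond, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  c + bond * (-cos(th) * bc + sin(th) * (cos(ch) * m - sin(ch) * n))
}

# Rodrigues rotation of point matrix `pts` (n x 3) about the axis through
# `origin` with unit direction `u`, by `ang` degrees
rotate_about_axis <- function(pts, origin, u, ang) {
  th <- ang * pi / 180
  co <- cos(th); si <- sin(th)
  p <- sweep(pts, 2, origin)
  dotu <- p %*% u
  crossu <- cbind(u[2] * p[, 3] - u[3] * p[, 2],
                  u[3] * p[, 1] - u[1] * p[, 3],
                  u[1] * p[, 2] - u[2] * p[, 1])
  r <- co * p + si * crossu + (1 - co) * (dotu %*% t(u))
  sweep(r, 2, origin, `+`)
}

# Kabsch least-squares superposition: rotation R and translation t such
# that moving %*% R + t best fits fixed (both n x 3)
kabsch_fit <- function(moving, fixed) {
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm)
  B <- sweep(fixed, 2, cf)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  t_vec <- cf - cm %*% R
  list(R = R, t = as.numeric(t_vec))
}

apply_fit <- function(pts, fit) {
  sweep(pts %*% fit$R, 2, fit$t, `+`)
}
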