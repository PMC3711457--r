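# Rigid-body helpers shared by frame fitting, parameter analysis and
# duplex rebuilding. Frames are stored as a list(R = 3x3, o = length-3):
# columns of R are the x, y, z unit axes in global coordinates; o is the
# origin in Angstrom.

.DEG <- pi / 180

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# Rotation about an arbitrary axis (Rodrigues); theta in radians.
.rotAxis <- function(u, theta) {
  u <- .normalize(u)
  ct <- cos(theta); st <- sin(theta)
  K <- matrix(c(0, u[3L], -u[2L],
                -u[3L], 0, u[1L],
                u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) * ct + st * K + (1 - ct) * tcrossprod(u)
}

.rotZ <- function(theta) .rotAxis(c(0, 0, 1), theta)
.rotY <- function(theta) .rotAxis(c(0, 1, 0), theta)

# Signed angle from a to b about axis (all in global coordinates).
.angleAbout <- function(a, b, axis) {
  atan2(sum(.cross(a, b) * axis), sum(a * b))
}

.isRotation <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3L))) < tol &&
    abs(det(R) - 1) < tol
}

.assertFrame <- function(frame) {
  if (!.isRotation(frame$R))
    stop("frame axes are not a proper rotation (orthonormal, det +1)")
  if (length(frame$o) != 3L || any(!is.finite(frame$o)))
    stop("frame origin must be a finite 3-vector")
  invisible(frame)
}

# y/z reversal applied to the second base of a pair (antiparallel strands).
.FLIP <- diag(c(1, -1, -1))

## Mid-frame parameter scheme ------------------------------------------------
#
# Six rigid-body parameters between two frames, decomposed through the
# mid-frame: theta_z is the rotation about the shared z after the bend is
# split symmetrically; the bend magnitude Gamma is split into (theta_x,
# theta_y) by the phase angle measured from the hinge axis; translations are
# the origin displacement expressed in the mid-frame. For base-pair steps
# the six are (shift, slide, rise, tilt, roll, twist); for the two bases of
# a pair they are (shear, stretch, stagger, buckle, propeller, opening).
# The build direction is the exact closed-form inverse, so analysis and
# rebuilding round-trip to machine precision.

# params: c(dx, dy, dz, theta_x, theta_y, theta_z), Angstrom / degrees.
.rigidAnalyze <- function(f1, f2) {
  z1 <- f1$R[, 3L]; z2 <- f2$R[, 3L]
  cg <- min(1, max(-1, sum(z1 * z2)))
  gamma <- acos(cg)
  hingeRaw <- .cross(z1, z2)
  if (sqrt(sum(hingeRaw^2)) < 1e-9) {
    gamma <- 0
    hinge <- f1$R[, 1L]
  } else {
    hinge <- .normalize(hingeRaw)
  }
  A1 <- .rotAxis(hinge, gamma / 2) %*% f1$R
  A2 <- .rotAxis(hinge, -gamma / 2) %*% f2$R
  zm <- .normalize(A1[, 3L] + A2[, 3L])
  tau <- .angleAbout(A1[, 1L], A2[, 1L], zm)
  xm <- .normalize(A1[, 1L] + A2[, 1L])
  ym <- .cross(zm, xm)
  Rm <- cbind(xm, ym, zm, deparse.level = 0L)
  phi <- .angleAbout(hinge, ym, zm)
  disp <- as.vector(crossprod(Rm, f2$o - f1$o))
  list(par = c(disp,
               gamma * sin(phi) / .DEG,
               gamma * cos(phi) / .DEG,
               tau / .DEG),
       mid = list(R = Rm, o = (f1$o + f2$o) / 2))
}

# Exact inverse: place frame2 (and the mid-frame) from frame1 and params.
.rigidBuild <- function(f1, par) {
  thx <- par[4L] * .DEG; thy <- par[5L] * .DEG; tau <- par[6L] * .DEG
  gamma <- sqrt(thx^2 + thy^2)
  phi <- atan2(thx, thy)
  R2 <- f1$R %*% .rotZ(tau / 2 - phi) %*% .rotY(gamma) %*% .rotZ(tau / 2 + phi)
  Rm <- f1$R %*% .rotZ(tau / 2 - phi) %*% .rotY(gamma / 2) %*% .rotZ(phi)
  o2 <- f1$o + as.vector(Rm %*% par[1:3])
  list(f2 = list(R = R2, o = o2),
       mid = list(R = Rm, o = (f1$o + o2) / 2))
}

# Given the mid-frame and params, recover the two outer frames (used when
# splitting a base pair into its two base frames).
.rigidSplit <- function(mid, par) {
  thx <- par[4L] * .DEG; thy <- par[5L] * .DEG; tau <- par[6L] * .DEG
  gamma <- sqrt(thx^2 + thy^2)
  phi <- atan2(thx, thy)
  Mhalf <- .rotZ(tau / 2 - phi) %*% .rotY(gamma / 2) %*% .rotZ(phi)
  R1 <- mid$R %*% t(Mhalf)
  f1 <- list(R = R1, o = mid$o - as.vector(mid$R %*% par[1:3]) / 2)
  b <- .rigidBuild(f1, par)
  list(f1 = f1, f2 = b$f2)
}

## Least-squares superposition -----------------------------------------------

# Kabsch: rotation + translation (no scaling, no reflection) mapping x onto y
# (both n x 3). Returns R, t with y ~ x %*% t(R) + t, plus the fit RMSD.
.kabsch <- function(x, y) {
  if (nrow(x) < 3L) stop("superposition needs at least 3 atoms")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2L, cx); yc <- sweep(y, 2L, cy)
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cy - as.vector(R %*% cx)
  fitted <- xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - yc)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

# Random proper rotation (uniform via QR of a Gaussian matrix).
.randomRotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}
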