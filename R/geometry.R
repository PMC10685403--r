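## Low-level 3D geometry: vectors, rigid transforms, torsions, frames.
## All coordinates are Cartesian angstroms; all angles radians unless noted.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Create a rigid transform
#'
#' A rigid transform is a proper rotation plus a translation, acting on row
#' coordinate vectors as `x -> x %*% t(R) + t`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1 (within 1e-6).
#' @param translation numeric length-3 translation in angstroms.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be proper (det +1)", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal", call. = FALSE)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Compose two rigid transforms
#'
#' `compose_rigid(t2, t1)` is the transform "apply t1, then t2".
#'
#' @param t2,t1 `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_rigid <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' Draw a random rigid transform
#'
#' Rotation uniform over SO(3) (via quaternion draw), translation from a
#' zero-mean Gaussian. Uses the current RNG stream.
#'
#' @param translation_sd standard deviation of each translation component (A).
#' @return A `rigid_transform`.
#' @export
random_rigid <- function(translation_sd = 10) {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  rigid_transform(quat_to_rot(q), stats::rnorm(3, sd = translation_sd))
}

## points: n x 3 matrix (or length-3 vector)
transform_points <- function(points, tr) {
  if (is.null(dim(points))) {
    as.numeric(tr$rotation %*% points) + tr$translation
  } else {
    sweep(points %*% t(tr$rotation), 2, tr$translation, "+")
  }
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

## Quaternion (w,x,y,z) of a rotation matrix, sign-fixed to w >= 0.
rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q
}

## Intrinsic Z-Y-X Euler angles of R = Rz(a) %*% Ry(b) %*% Rx(c).
rot_to_euler_zyx <- function(R) {
  b <- -asin(max(-1, min(1, R[3, 1])))
  if (abs(abs(R[3, 1]) - 1) < 1e-10) {
    ## gimbal lock: fold everything into the first angle
    a <- atan2(-R[1, 2], R[2, 2])
    c <- 0
  } else {
    a <- atan2(R[2, 1], R[1, 1])
    c <- atan2(R[3, 2], R[3, 3])
  }
  c(a, b, c)
}

## Signed torsion angle p1-p2-p3-p4 in radians, IUPAC sign convention.
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

## Bond angle at p2 (p1-p2-p3), radians.
bond_angle <- function(p1, p2, p3) {
  u <- unit(p1 - p2)
  v <- unit(p3 - p2)
  acos(max(-1, min(1, sum(u * v))))
}

## NeRF placement: position of atom D given A-B-C, |C-D|, angle(B,C,D) and
## torsion(A,B,C,D).
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  c + (-bond * cos(angle)) * bc +
    (bond * sin(angle) * cos(torsion)) * m -
    (bond * sin(angle) * sin(torsion)) * n
}

## Gram-Schmidt residue frame from backbone atoms.
## x-axis along CA->C, y in the N-CA-C plane, z completes a right-handed set.
backbone_frame <- function(n, ca, c) {
  v1 <- c - ca
  v2 <- n - ca
  if (vnorm(v1) < 1e-8 || vnorm(v2) < 1e-8)
    stop("degenerate backbone frame: coincident atoms", call. = FALSE)
  e1 <- unit(v1)
  u2 <- v2 - sum(v2 * e1) * e1
  if (vnorm(u2) < 1e-8)
    stop("degenerate backbone frame: collinear N, CA, C", call. = FALSE)
  e2 <- unit(u2)
  e3 <- cross3(e1, e2)
  cbind(e1, e2, e3, deparse.level = 0)
}

## Kabsch: rotation + translation superposing mobile (n x 3) onto target.
## Returns list(R, t) with aligned = mobile %*% R + rep(t) (row convention).
kabsch <- function(mobile, target) {
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(target, 2, ct)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  t <- ct - as.numeric(cm %*% R)
  list(R = R, t = t)
}

## deterministic RNG scope: run expr with a local seed, restore global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Small stable string hash (31-bit polynomial) for seeds and layout hashes.
## Kept below 2^31 so results are valid set.seed() inputs.
string_hash31 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  h
}
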