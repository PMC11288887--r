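`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- basic vector helpers (3-vectors as numeric(3), point sets as n x 3) ----

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle at vertex b of the three points a-b-c, in degrees
#' @keywords internal
angle_deg <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Signed dihedral angle a-b-c-d in degrees, IUPAC sign convention
#' @keywords internal
dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

#' Place an atom from internal coordinates (natural extension reference frame)
#'
#' Given three reference positions `a`, `b`, `c`, returns the position `d`
#' with bond length |c-d| = `bond`, angle b-c-d = `angle` (degrees) and
#' dihedral a-b-c-d = `torsion` (degrees).
#' @keywords internal
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## ---- rigid transforms ----------------------------------------------------

#' Create a rigid transform
#'
#' A rigid transform couples a proper rotation matrix with a translation and
#' acts on row-wise coordinate matrices as `x %*% t(R) + t`. It is the unit
#' of all six-degree-of-freedom sampling and of repeat propagation.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric 3-vector, Angstrom.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$R, 6))
  cat("  translation:", paste(round(x$t, 4), collapse = " "), "\n")
  invisible(x)
}

#' Identity transform
#' @export
rt_identity <- function() rigid_transform()

#' Compose two rigid transforms (apply `t2` first, then `t1`)
#' @param t1,t2 `rigid_transform` objects.
#' @export
rt_compose <- function(t1, t2) {
  rigid_transform(t1$R %*% t2$R, as.numeric(t1$R %*% t2$t) + t1$t)
}

#' Inverse of a rigid transform
#' @param tr a `rigid_transform`.
#' @export
rt_inverse <- function(tr) {
  rigid_transform(t(tr$R), as.numeric(-t(tr$R) %*% tr$t))
}

#' Integer power of a rigid transform
#'
#' `rt_power(tr, k)` equals `k` successive compositions of `tr`; `k = 0`
#' returns the identity and negative `k` powers the inverse.
#' @param tr a `rigid_transform`.
#' @param k integer.
#' @export
rt_power <- function(tr, k) {
  k <- as.integer(k)
  if (k < 0) return(rt_power(rt_inverse(tr), -k))
  out <- rt_identity()
  while (k > 0L) {
    out <- rt_compose(tr, out)
    k <- k - 1L
  }
  out
}

#' Apply a rigid transform to coordinates
#'
#' @param tr a `rigid_transform`.
#' @param x numeric 3-vector, an n x 3 matrix, or a `backbone_model`.
#' @return same shape as `x`.
#' @export
rt_apply <- function(tr, x) {
  if (inherits(x, "backbone_model")) {
    x$xyz <- rt_apply(tr, x$xyz)
    return(x)
  }
  if (is.matrix(x)) {
    sweep(x %*% t(tr$R), 2, tr$t, "+")
  } else {
    as.numeric(tr$R %*% x) + tr$t
  }
}

## ---- six degrees of freedom ---------------------------------------------

#' Six rigid-body degrees of freedom
#'
#' Translations in Angstrom, rotations in degrees using the intrinsic
#' z-y-x Euler convention (first rotate about z by `rz`, then about the new
#' y by `ry`, then about the new x by `rx`).
#'
#' @param tx,ty,tz translations, Angstrom.
#' @param rx,ry,rz rotations, degrees.
#' @export
six_dof <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  structure(list(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz),
            class = "six_dof")
}

rot_x <- function(a) {
  a <- deg2rad(a)
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}
rot_y <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}
rot_z <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Convert six degrees of freedom to a rigid transform
#' @param dof a `six_dof` object.
#' @export
dof_to_transform <- function(dof) {
  stopifnot(inherits(dof, "six_dof"))
  R <- rot_z(dof$rz) %*% rot_y(dof$ry) %*% rot_x(dof$rx)
  rigid_transform(R, c(dof$tx, dof$ty, dof$tz))
}

#' Recover six degrees of freedom from a rigid transform
#'
#' Inverse of [dof_to_transform()]; exact away from gimbal lock
#' (`|ry| = 90` degrees).
#' @param tr a `rigid_transform`.
#' @export
transform_to_dof <- function(tr) {
  R <- tr$R
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) < 1e-9) {
    rz <- atan2(-R[1, 2], R[2, 2])
    rx <- 0
  } else {
    rz <- atan2(R[2, 1], R[1, 1])
    rx <- atan2(R[3, 2], R[3, 3])
  }
  six_dof(tr$t[1], tr$t[2], tr$t[3],
          rad2deg(rx), rad2deg(ry), rad2deg(rz))
}

## ---- Kabsch superposition -------------------------------------------------

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the rigid transform minimising the RMSD between `mobile` and `ref`
#' point sets, via SVD of the covariance matrix with the usual determinant
#' correction so only proper rotations are returned.
#'
#' @param mobile,ref n x 3 coordinate matrices, matched row-wise, n >= 3.
#' @return list with `transform` (a [rigid_transform()] mapping mobile onto
#'   ref), `rmsd` (Angstrom) and `degenerate` (TRUE when the points are
#'   collinear so the rotation is not unique, though the RMSD still is).
#' @export
superpose_kabsch <- function(mobile, ref) {
  mobile <- as.matrix(mobile)
  ref <- as.matrix(ref)
  stopifnot(ncol(mobile) == 3, ncol(ref) == 3)
  if (nrow(mobile) != nrow(ref)) stop("point sets must have equal length")
  if (nrow(mobile) < 3) stop("need at least 3 points")
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm)
  B <- sweep(ref, 2, cr)
  H <- crossprod(A, B)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  tr <- rigid_transform(R, cr - as.numeric(R %*% cm))
  list(transform = tr, rmsd = rmsd, degenerate = degenerate)
}

#' Root-mean-square deviation between matched coordinate sets (no fitting)
#' @param a,b n x 3 matrices.
#' @export
rmsd_raw <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(identical(dim(a), dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}
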