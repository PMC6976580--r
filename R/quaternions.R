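## Unit-quaternion algebra, scalar-first convention (w, x, y, z).
##
## Quaternions represent active rotations mapping the nitroxide principal
## axes system (PAS) into the laboratory (or molecular) frame. Composition is
## right-to-left: quatMultiply(a, b) is "apply b, then a". All functions are
## vectorised over rows of N x 4 matrices.

.asQuatMatrix <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (ncol(q) != 4) stop("quaternions must have 4 columns (w, x, y, z)")
  q
}

#' Quaternion product
#'
#' Hamilton product of two quaternion arrays (scalar-first). Rows are
#' recycled if one argument has a single row.
#'
#' @param a,b Quaternions as length-4 vectors or N x 4 matrices.
#' @return N x 4 matrix of products `a * b` (apply `b`, then `a`).
#' @export
quatMultiply <- function(a, b) {
  a <- .asQuatMatrix(a); b <- .asQuatMatrix(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  cbind(w = w, x = x, y = y, z = z)
}

#' Quaternion conjugate (inverse for unit quaternions)
#' @param q Quaternion vector or matrix.
#' @return Matrix of conjugates.
#' @export
quatConjugate <- function(q) {
  q <- .asQuatMatrix(q)
  cbind(w = q[, 1], x = -q[, 2], y = -q[, 3], z = -q[, 4])
}

#' Rotate 3-vectors by quaternions
#'
#' @param q Unit quaternion(s), N x 4 or length 4.
#' @param v 3-vector or N x 3 matrix.
#' @return N x 3 matrix of rotated vectors.
#' @export
quatRotate <- function(q, v) {
  q <- .asQuatMatrix(q)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  n <- max(nrow(q), nrow(v))
  if (nrow(q) == 1L && n > 1L) q <- q[rep(1L, n), , drop = FALSE]
  if (nrow(v) == 1L && n > 1L) v <- v[rep(1L, n), , drop = FALSE]
  ## v' = v + 2 q_v x (q_v x v + w v)
  tx <- q[, 3] * v[, 3] - q[, 4] * v[, 2] + q[, 1] * v[, 1]
  ty <- q[, 4] * v[, 1] - q[, 2] * v[, 3] + q[, 1] * v[, 2]
  tz <- q[, 2] * v[, 2] - q[, 3] * v[, 1] + q[, 1] * v[, 3]
  cbind(v[, 1] + 2 * (q[, 3] * tz - q[, 4] * ty),
        v[, 2] + 2 * (q[, 4] * tx - q[, 2] * tz),
        v[, 3] + 2 * (q[, 2] * ty - q[, 3] * tx))
}

#' Convert quaternions to rotation matrices
#'
#' @param q Unit quaternion (length 4) or N x 4 matrix.
#' @return A 3 x 3 matrix for a single quaternion, else a 3 x 3 x N array.
#' @export
quatToMatrix <- function(q) {
  q <- .asQuatMatrix(q)
  one <- function(qi) {
    w <- qi[1]; x <- qi[2]; y <- qi[3]; z <- qi[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
      nrow = 3, byrow = TRUE)
  }
  if (nrow(q) == 1L) return(one(q[1, ]))
  vapply(seq_len(nrow(q)), function(i) one(q[i, ]), matrix(0, 3, 3))
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Shepperd's method; the returned quaternion has non-negative scalar part.
#'
#' @param R Orthogonal 3 x 3 matrix with determinant +1.
#' @return Length-4 quaternion (w, x, y, z).
#' @export
quatFromMatrix <- function(R) {
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
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' Axis-angle (exponential-map) conversions
#'
#' `quatToAxisAngle` returns per-row rotation vectors (axis scaled by angle,
#' radians); `quatFromAxisAngle` is its inverse. These implement the
#' logarithm/exponential maps used by the tumbling-rescaling algorithm.
#'
#' @param q Quaternions, N x 4.
#' @return N x 3 matrix of rotation vectors.
#' @export
quatToAxisAngle <- function(q) {
  q <- .asQuatMatrix(q)
  w <- pmin(pmax(q[, 1], -1), 1)
  s <- sqrt(pmax(1 - w^2, 0))
  angle <- 2 * atan2(s, w)
  ## small-angle safe axis scaling: rotvec = 2*asin(s)/s * q_v, limit 2*q_v
  scale <- ifelse(s < 1e-12, 2, angle / s)
  q[, 2:4, drop = FALSE] * scale
}

#' @rdname quatToAxisAngle
#' @param rv Rotation vectors, N x 3 (axis * angle, radians).
#' @export
quatFromAxisAngle <- function(rv) {
  if (is.null(dim(rv))) rv <- matrix(rv, nrow = 1)
  angle <- sqrt(rowSums(rv^2))
  half <- angle / 2
  s <- ifelse(angle < 1e-12, 0.5, sin(half) / angle)
  cbind(w = cos(half), x = rv[, 1] * s, y = rv[, 2] * s, z = rv[, 3] * s)
}

#' Sign-align a quaternion sequence
#'
#' Flips individual quaternion signs so that consecutive rows satisfy
#' `q_k . q_{k+1} >= 0`, removing the double-cover ambiguity after file
#' loading or PAS extraction.
#'
#' @param q N x 4 quaternion matrix.
#' @return Sign-aligned matrix.
#' @export
quatAlignSigns <- function(q) {
  q <- .asQuatMatrix(q)
  if (nrow(q) < 2L) return(q)
  dots <- rowSums(q[-nrow(q), , drop = FALSE] * q[-1, , drop = FALSE])
  flips <- cumprod(ifelse(dots < 0, -1, 1))
  q[-1, ] <- q[-1, , drop = FALSE] * flips
  q
}

## Sequential right-composition q_{k+1} = q_k * dq_k, delegated to C++.
.quatAccumulate <- function(q0, dq) {
  q_accumulate_cpp(as.numeric(q0), .asQuatMatrix(dq))
}
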