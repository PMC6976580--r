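## Spin operators and the electron-nuclear Hamiltonian.
##
## The spin system is an electron S = 1/2 coupled to the nitroxide nitrogen
## (I = 1 for 14N, I = 1/2 for 15N). Basis ordering: electron mS = +1/2
## block first, nuclear states descending in mI within each block, giving
## composite dimension 2*(2I+1) (6 x 6 for 14N).

.angularMomentum <- function(j) {
  m <- seq(j, -j, by = -1)
  d <- length(m)
  Jz <- diag(m)
  Jp <- matrix(0, d, d)
  if (d > 1) {
    for (k in seq_len(d - 1)) {
      mk <- m[k + 1]
      Jp[k, k + 1] <- sqrt(j * (j + 1) - mk * (mk + 1))
    }
  }
  Jm <- t(Jp)
  list(Jx = (Jp + Jm) / 2, Jy = (Jp - Jm) / (2i), Jz = Jz + 0i,
       Jp = Jp + 0i, Jm = Jm + 0i)
}

#' Build the spin operator set for the composite electron-nuclear space
#'
#' Returns Sx, Sy, Sz, Sp (S+), Sm (S-), the analogous nuclear operators and
#' the identity, as complex matrices of dimension `2 * (2I + 1)` (6 for
#' I = 1, 4 for I = 1/2). The operators satisfy the angular-momentum algebra
#' `[Sx, Sy] = i Sz` (and cyclic) exactly, electron and nuclear operators
#' commute, and `Sp` is the Hermitian conjugate of `Sm`.
#'
#' @param nuclearSpin Nuclear spin quantum number: 1 or 0.5. A
#'   [SpinSystem-class] may be given instead.
#' @return An [OperatorSet-class].
#' @examples
#' ops <- spinOperators(1)
#' ops@dimension  # 6
#' @export
spinOperators <- function(nuclearSpin) {
  if (is(nuclearSpin, "SpinSystem")) nuclearSpin <- nuclearSpin@nuclearSpin
  if (!isTRUE(nuclearSpin %in% c(0.5, 1)))
    stop("unsupported nuclear spin: ", nuclearSpin,
         " (supported: 1 for 14N, 0.5 for 15N)")
  S <- .angularMomentum(0.5)
  I <- .angularMomentum(nuclearSpin)
  dI <- nrow(I$Jz)
  eS <- diag(2) + 0i
  eI <- diag(dI) + 0i
  ops <- list(
    Sx = kronecker(S$Jx, eI), Sy = kronecker(S$Jy, eI),
    Sz = kronecker(S$Jz, eI), Sp = kronecker(S$Jp, eI),
    Sm = kronecker(S$Jm, eI),
    Ix = kronecker(eS, I$Jx), Iy = kronecker(eS, I$Jy),
    Iz = kronecker(eS, I$Jz), Ip = kronecker(eS, I$Jp),
    Im = kronecker(eS, I$Jm),
    E = kronecker(eS, eI))
  new("OperatorSet", operators = ops, dimension = 2L * dI,
      nuclearSpin = nuclearSpin)
}

## Rotation-matrix elements for a batch of quaternions, N x 9 column-major
## (R11, R21, R31, R12, ..., R33); used for vectorised tensor rotation.
.rotationElements <- function(q) {
  q <- .asQuatMatrix(q)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(R11 = 1 - 2 * (y^2 + z^2), R21 = 2 * (x * y + w * z),
        R31 = 2 * (x * z - w * y),
        R12 = 2 * (x * y - w * z), R22 = 1 - 2 * (x^2 + z^2),
        R32 = 2 * (y * z + w * x),
        R13 = 2 * (x * z + w * y), R23 = 2 * (y * z - w * x),
        R33 = 1 - 2 * (x^2 + y^2))
}

#' Rotate a PAS tensor into the laboratory frame
#'
#' Computes `R T R^-1` for a (diagonal) principal-axes tensor and a rotation
#' given as a unit quaternion. Similarity transformation preserves the
#' eigenvalues, which is asserted by the unit tests.
#'
#' @param tensor 3 x 3 symmetric matrix in the PAS.
#' @param q Unit quaternion mapping PAS to lab.
#' @return 3 x 3 matrix in the laboratory frame.
#' @export
rotateTensor <- function(tensor, q) {
  R <- quatToMatrix(q)
  R %*% tensor %*% t(R)
}

#' Time-dependent electron-nuclear Hamiltonian
#'
#' Assembles the nitroxide spin Hamiltonian for one orientation of the
#' principal axes system,
#' `H = w0 Sz + muB/hbar S.(R gAniso R^-1).B0 + Aiso S.I
#'    + S.(R AAniso R^-1).I`,
#' in angular-frequency units (rad/s). With `frame = "rotating"` the
#' isotropic electron Zeeman term `w0 Sz` is removed and the terms that do
#' not commute with Sz (off-resonant by the 9.45 GHz carrier in the
#' laboratory frame) are dropped, yielding the standard high-field secular
#' form `H = dwg Sz + Sz (ax Ix + ay Iy + az Iz)` used by the propagation
#' engine.
#'
#' @param spec A [SpinSystem-class].
#' @param rotation Unit quaternion (length 4), PAS to lab.
#' @param field A [FieldConfig-class].
#' @param frame `"rotating"` (default) or `"lab"`.
#' @return Hermitian complex matrix of dimension `2*(2I+1)`, rad/s.
#' @export
spinHamiltonian <- function(spec, rotation, field = fieldConfig(),
                            frame = c("rotating", "lab")) {
  frame <- match.arg(frame)
  stopifnot(is(spec, "SpinSystem"), is(field, "FieldConfig"))
  rotation <- as.numeric(rotation)
  if (abs(sqrt(sum(rotation^2)) - 1) > 1e-8)
    stop("rotation must be a unit quaternion (|q| = 1 within 1e-8)")
  ops <- spinOperators(spec@nuclearSpin)@operators
  gA <- rotateTensor(gAniso(spec), rotation)
  aA <- rotateTensor(aAniso(spec), rotation) * 2e6 * pi     # MHz -> rad/s
  aI <- aIso(spec) * 2e6 * pi
  zeeman <- physicalConstants$muB * field@B0 / physicalConstants$hbar
  w0 <- gIso(spec) * zeeman
  Svec <- list(ops$Sx, ops$Sy, ops$Sz)
  Ivec <- list(ops$Ix, ops$Iy, ops$Iz)
  if (frame == "lab") {
    H <- w0 * ops$Sz
    for (i in 1:3) H <- H + zeeman * gA[i, 3] * Svec[[i]]
    H <- H + aI * (ops$Sx %*% ops$Ix + ops$Sy %*% ops$Iy + ops$Sz %*% ops$Iz)
    for (i in 1:3) for (j in 1:3)
      H <- H + aA[i, j] * (Svec[[i]] %*% Ivec[[j]])
  } else {
    H <- zeeman * gA[3, 3] * ops$Sz
    a <- c(aA[3, 1], aA[3, 2], aI + aA[3, 3])
    for (j in 1:3) H <- H + a[j] * (ops$Sz %*% Ivec[[j]])
  }
  H
}

#' Secular coupling coefficients along a trajectory
#'
#' For every frame, the four scalar coefficients of the rotating-frame
#' secular Hamiltonian `H(t) = cg(t) Sz + Sz (ax(t) Ix + ay(t) Iy +
#' az(t) Iz)`: the anisotropic-Zeeman frequency shift `cg` and the
#' laboratory z row of the full hyperfine tensor (isotropic part included in
#' `az`). All values in rad/s. This N x 4 matrix is the only input the
#' propagation and Redfield engines need from the orientational trajectory.
#'
#' @param traj An [OrientationTrajectory-class].
#' @param spec A [SpinSystem-class].
#' @param field A [FieldConfig-class].
#' @return N x 4 numeric matrix with columns `cg`, `ax`, `ay`, `az`.
#' @export
secularCoefficients <- function(traj, spec, field = fieldConfig()) {
  stopifnot(is(traj, "OrientationTrajectory"), is(spec, "SpinSystem"))
  .secularCoefficientsQ(traj@quaternions, spec, field)
}

## fast path on a raw quaternion matrix (quaternion signs are irrelevant
## for the rotation-matrix elements, so no alignment is needed); qrot
## applies an optional fixed global pre-rotation
.secularCoefficientsQ <- function(q, spec, field, qrot = c(1, 0, 0, 0)) {
  out <- secular_coef_cpp(.asQuatMatrix(q), as.numeric(qrot),
                          spec@gPrincipal - gIso(spec),
                          (spec@aPrincipal - aIso(spec)) * 2e6 * pi,
                          physicalConstants$muB * field@B0 /
                            physicalConstants$hbar,
                          aIso(spec) * 2e6 * pi)
  colnames(out) <- c("cg", "ax", "ay", "az")
  out
}
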