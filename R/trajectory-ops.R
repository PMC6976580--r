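## Orientational-trajectory operations: PAS extraction from coordinates,
## tumbling/internal decomposition, molecular-frame tumbling rescaling, and
## correlation-function analyses.

## Lag-averaged cross-correlation <x(t) y(t+tau)> for tau = 0..maxLag via
## FFT, with lag-dependent normalisation (no zero-padding bias).
.fftCrossCorr <- function(x, y, maxLag) {
  n <- length(x)
  stopifnot(length(y) == n, maxLag < n)
  L <- stats::nextn(n + maxLag + 1, 2)
  fx <- stats::fft(c(x, numeric(L - n)))
  fy <- stats::fft(c(y, numeric(L - n)))
  cc <- Re(stats::fft(Conj(fx) * fy, inverse = TRUE)) / L
  cc[seq_len(maxLag + 1)] / (n - 0:maxLag)
}

## symmetrised 4 x 4 x (maxLag+1) correlation array of a coefficient
## matrix, with forward FFTs computed once per column. Long series are
## split into segments (>= 32x the lag range) so transform lengths stay
## bounded; cross-segment start pairs are discarded, a negligible loss for
## lag << segment length, and each segment keeps its own lag-dependent
## normalisation.
.coefCorrelations <- function(dc, maxLag) {
  n <- nrow(dc)
  segLen <- max(32L * (maxLag + 1L), 65536L)
  nSeg <- max(1L, n %/% segLen)
  bounds <- floor(seq(0, n, length.out = nSeg + 1))
  corr <- array(0, c(4, 4, maxLag + 1))
  wTot <- numeric(maxLag + 1)
  for (s in seq_len(nSeg)) {
    seg <- dc[(bounds[s] + 1):bounds[s + 1], , drop = FALSE]
    m <- nrow(seg)
    L <- stats::nextn(m + maxLag + 1, 2)
    fts <- lapply(1:4, function(p) stats::fft(c(seg[, p], numeric(L - m))))
    w <- m - 0:maxLag          # pair counts at each lag
    for (p in 1:4) for (q in p:4) {
      prod <- Conj(fts[[p]]) * fts[[q]]
      if (q > p) prod <- (prod + Conj(fts[[q]]) * fts[[p]]) / 2
      cc <- Re(stats::fft(prod, inverse = TRUE))[seq_len(maxLag + 1)] / L
      corr[p, q, ] <- corr[p, q, ] + cc
      if (q > p) corr[q, p, ] <- corr[q, p, ] + cc
    }
    wTot <- wTot + w
  }
  for (i in seq_len(maxLag + 1)) corr[, , i] <- corr[, , i] / wTot[i]
  corr
}

## Average rank-2 (P2) autocorrelation of the three body axes of a
## quaternion trajectory; returns values for lags 0..maxLag.
.rank2AxisCorrelation <- function(q, maxLag) {
  R <- .rotationElements(q)
  out <- numeric(maxLag + 1)
  for (axis in 0:2) {          # body axis = column of R
    u <- R[, 3 * axis + (1:3), drop = FALSE]
    dot2 <- numeric(maxLag + 1)
    for (i in 1:3) for (j in i:3) {
      p <- u[, i] * u[, j]
      w <- if (i == j) 1 else 2
      dot2 <- dot2 + w * .fftCrossCorr(p, p, maxLag)
    }
    out <- out + (3 * dot2 - 1) / 2
  }
  out / 3
}

#' Extract the nitroxide PAS trajectory from ring-atom coordinates
#'
#' Builds the principal-axes frame from per-frame coordinates of the
#' nitroxide nitrogen, the oxygen and the two ring carbons bonded to the
#' nitrogen: x along the N-O bond, z along the normal of the plane spanned
#' by the two N-C bonds (orthogonalised against x, sign-continuous across
#' frames), y = z cross x.
#'
#' @param frames Numeric array `nFrames x 4 x 3`; atom order N, O, C1, C2.
#' @param deltaPs Frame spacing in picoseconds.
#' @return An [OrientationTrajectory-class] (PAS to lab).
#' @export
extractPas <- function(frames, deltaPs = 1) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[2] == 4, dim(frames)[3] == 3)
  n <- dim(frames)[1]
  q <- matrix(0, n, 4)
  zPrev <- NULL
  for (k in seq_len(n)) {
    Natom <- frames[k, 1, ]; O <- frames[k, 2, ]
    C1 <- frames[k, 3, ]; C2 <- frames[k, 4, ]
    x <- O - Natom
    nx <- sqrt(sum(x^2))
    if (nx < 1e-9) stop("degenerate N-O bond in frame ", k)
    x <- x / nx
    nrm <- pracma::cross(C1 - Natom, C2 - Natom)
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-9)
      stop("colinear N/C1/C2 atoms (degenerate ring normal) in frame ", k)
    z <- nrm / nn
    z <- z - sum(z * x) * x
    z <- z / sqrt(sum(z^2))
    if (!is.null(zPrev) && sum(z * zPrev) < 0) z <- -z
    zPrev <- z
    y <- pracma::cross(z, x)
    q[k, ] <- quatFromMatrix(cbind(x, y, z))
  }
  orientationTrajectory(q, deltaPs = deltaPs)
}

## Kabsch: least-squares rotation carrying reference coordinates onto the
## frame coordinates (reflection guarded to det +1).
.kabsch <- function(ref, coords) {
  refC <- sweep(ref, 2, colMeans(ref))
  xC <- sweep(coords, 2, colMeans(coords))
  C <- t(xC) %*% refC
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Decompose a PAS trajectory into global tumbling and internal motion
#'
#' The molecule-to-lab rotation `Q(t)` is obtained by optimal least-squares
#' superposition of the per-frame fit-atom coordinates onto a reference
#' structure; the internal part is `r(t) = Q(t)^-1 o R(t)` so that
#' `R(t) = Q(t) o r(t)` holds per frame.
#'
#' @param traj Full PAS-to-lab [OrientationTrajectory-class] R(t).
#' @param reference `m x 3` matrix of reference (molecular-frame) fit atoms.
#' @param frames `nFrames x m x 3` array of the same atoms per frame.
#' @return A [DecomposedTrajectory-class].
#' @export
decomposeTrajectory <- function(traj, reference, frames) {
  stopifnot(is(traj, "OrientationTrajectory"),
            length(dim(frames)) == 3, dim(frames)[3] == 3)
  m <- nrow(reference)
  if (m < 3) stop("at least 3 fit atoms are required")
  ## colinearity check on the reference
  refC <- sweep(reference, 2, colMeans(reference))
  if (qr(refC)$rank < 2)
    stop("fit atoms are colinear; the superposition rotation is degenerate")
  n <- dim(frames)[1]
  if (n != nFrames(traj)) stop("frames and trajectory lengths differ")
  Qm <- matrix(0, n, 4)
  for (k in seq_len(n))
    Qm[k, ] <- quatFromMatrix(.kabsch(reference, frames[k, , ]))
  Qm <- quatAlignSigns(Qm)
  rQ <- quatMultiply(quatConjugate(Qm), traj@quaternions)
  decomposedTrajectory(
    orientationTrajectory(Qm, trajectoryDelta(traj), normalize = TRUE),
    orientationTrajectory(rQ, trajectoryDelta(traj), normalize = TRUE))
}

#' Compose global and internal trajectories
#'
#' `R(t) = Q(t) o r(t)`; the ground-truth decomposition is retained in the
#' returned object. Use [fullTrajectory()] to materialise R(t).
#'
#' @param global,internal [OrientationTrajectory-class] objects of equal
#'   length and step.
#' @return A [DecomposedTrajectory-class].
#' @export
composeTrajectory <- function(global, internal) {
  if (nFrames(global) != nFrames(internal))
    stop("global and internal trajectories differ in length")
  if (trajectoryDelta(global) != trajectoryDelta(internal))
    stop("global and internal trajectories differ in time step")
  decomposedTrajectory(global, internal)
}

#' Full PAS-to-lab trajectory of a decomposition
#' @param decomposed A [DecomposedTrajectory-class].
#' @return The composed [OrientationTrajectory-class] `R(t) = Q(t) o r(t)`.
#' @export
fullTrajectory <- function(decomposed) {
  stopifnot(is(decomposed, "DecomposedTrajectory"))
  q <- quatMultiply(decomposed@global@quaternions,
                    decomposed@internal@quaternions)
  orientationTrajectory(q, trajectoryDelta(decomposed), normalize = TRUE)
}

#' Rescale the overall tumbling of a decomposed trajectory
#'
#' Implements the pseudo-trajectory construction that speeds up or slows
#' down the global tumbling while leaving internal label dynamics and the
#' tumbling anisotropy untouched: the elementary rotations
#' `e_k = Q(t_k)^-1 o Q(t_{k+1})` are expressed in the molecular frame,
#' converted to axis-angle form, their angles multiplied by `lambda`, and
#' the sequence re-accumulated from `Q'(0) = Q(0)`. Because elementary
#' angles scale linearly while the rotational diffusion constant scales with
#' their variance, the tumbling correlation time changes by `lambda^-2`
#' (lambda = 0.5 slows tumbling 4-fold).
#'
#' @param decomposed A [DecomposedTrajectory-class].
#' @param lambda Positive scale factor (`< 1` slows tumbling, `> 1` speeds
#'   it up; 0 freezes the global part).
#' @return A [DecomposedTrajectory-class] with rescaled global part.
#' @export
rescaleTumbling <- function(decomposed, lambda) {
  stopifnot(is(decomposed, "DecomposedTrajectory"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("lambda must be a single non-negative number")
  Q <- decomposed@global@quaternions
  n <- nrow(Q)
  elem <- quatMultiply(quatConjugate(Q[-n, , drop = FALSE]),
                       Q[-1, , drop = FALSE])
  rv <- quatToAxisAngle(elem) * lambda
  Qs <- .quatAccumulate(Q[1, ], quatFromAxisAngle(rv))
  decomposedTrajectory(
    orientationTrajectory(Qs, trajectoryDelta(decomposed), normalize = TRUE),
    decomposed@internal)
}

#' Rank-2 (P2) orientational autocorrelation of a vector trajectory
#'
#' `C(tau) = <P2(u(t) . u(t+tau))>` averaged over all valid start frames
#' (stride 1), with `P2(x) = (3x^2 - 1)/2`; `C(0) = 1` for unit vectors.
#'
#' @param vectors `n x 3` matrix of unit vectors, one per frame.
#' @param maxLag Maximum lag in frames (`< n`).
#' @param deltaPs Frame spacing, ps.
#' @return A [CorrelationFunction-class].
#' @export
p2Correlation <- function(vectors, maxLag, deltaPs = 1) {
  if (is.null(dim(vectors)) || nrow(vectors) < 2L)
    stop("vectors must be an n x 3 matrix with n >= 2")
  n <- nrow(vectors)
  if (maxLag >= n) stop("maxLag must be smaller than the trajectory length")
  u <- vectors / sqrt(rowSums(vectors^2))
  dot2 <- numeric(maxLag + 1)
  for (i in 1:3) for (j in i:3) {
    p <- u[, i] * u[, j]
    w <- if (i == j) 1 else 2
    dot2 <- dot2 + w * .fftCrossCorr(p, p, maxLag)
  }
  correlationFunction((0:maxLag) * deltaPs, (3 * dot2 - 1) / 2,
                      normalized = TRUE)
}

#' Estimate the overall tumbling correlation time
#'
#' Averages the P2 autocorrelations of the three molecular axes of the
#' global rotation and fits a single exponential `exp(-tau/tauRot)` over
#' lags `[0, 5 * tauGuess]` with log-linear initialisation (`tauGuess` from
#' the 1/e crossing). The estimator targets the rank-2 orientational
#' correlation time probed by ESR; for isotropic Brownian rotation it equals
#' `1/(6D)`.
#'
#' @param global [OrientationTrajectory-class] of the global (tumbling)
#'   rotation Q(t).
#' @param maxLagPs Maximum lag used for the correlation function, ps;
#'   default is 1/20 of the trajectory (a warning is issued when the
#'   trajectory is shorter than 50x the recovered correlation time).
#' @return List with `tauRotNs`, `residual` (RMS of fit), and `corr` (the
#'   [CorrelationFunction-class] actually fitted).
#' @export
estimateTauRot <- function(global, maxLagPs = NULL) {
  stopifnot(is(global, "OrientationTrajectory"))
  n <- nFrames(global)
  delta <- trajectoryDelta(global)
  if (is.null(maxLagPs)) maxLagPs <- n * delta / 20
  maxLag <- min(n - 2L, max(10L, floor(maxLagPs / delta)))
  cf <- .rank2AxisCorrelation(global@quaternions, maxLag)
  lag <- (0:maxLag) * delta
  if (min(cf) > 0.8)
    stop("orientational correlation function does not decay; ",
         "the trajectory appears static (tauRot = Inf)")
  ## 1/e crossing as initial guess
  below <- which(cf < exp(-1))
  tauGuess <- if (length(below)) lag[below[1]] else maxLag * delta / 3
  keep <- lag <= 5 * tauGuess
  lagF <- lag[keep]; cfF <- cf[keep]
  fit <- minpack.lm::nlsLM(cfF ~ exp(-lagF / tau),
                           start = list(tau = tauGuess),
                           lower = delta / 100,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  tau <- coef(fit)[["tau"]]
  if (n * delta < 50 * tau)
    warning("trajectory is shorter than 50x the recovered correlation time; ",
            "the tumbling estimate may be unreliable")
  list(tauRotNs = tau / 1000,
       residual = sqrt(mean(residuals(fit)^2)),
       corr = correlationFunction(lag, cf, normalized = TRUE))
}

#' Dihedral-angle temporal correlation function
#'
#' `gamma(tau) = <cos(delta chi(tau))>` where `delta chi` is the periodic
#' angular difference over lag `tau`; `gamma(0) = 1`. For rotameric jump
#' dynamics the long-lag plateau reports the equilibrium spread of the
#' rotamer populations.
#'
#' @param series An [AngleSeries-class].
#' @param maxLag Maximum lag in frames.
#' @return A [CorrelationFunction-class].
#' @export
dihedralGamma <- function(series, maxLag) {
  stopifnot(is(series, "AngleSeries"))
  n <- length(series@values)
  if (maxLag >= n) stop("maxLag must be smaller than the series length")
  rad <- series@values * pi / 180
  g <- .fftCrossCorr(cos(rad), cos(rad), maxLag) +
    .fftCrossCorr(sin(rad), sin(rad), maxLag)
  correlationFunction((0:maxLag) * series@deltaPs, g, normalized = TRUE)
}

#' Plateau (order parameter squared) of a correlation function
#'
#' Mean of `C(tau)` over the final 10 percent of the computed lag range; a
#' simple plateau estimator for `S^2`.
#'
#' @param corr A [CorrelationFunction-class].
#' @return Scalar plateau estimate.
#' @export
correlationPlateau <- function(corr) {
  stopifnot(is(corr, "CorrelationFunction"))
  v <- corr@values
  mean(v[seq(max(1L, floor(0.9 * length(v))), length(v))])
}
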