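## Seeded generators of orientational trajectories with the statistical
## structure typical of spin-labeled protein MD data: nanosecond global
## tumbling (isotropic or axially anisotropic), fast restricted internal
## label motion (cone, discrete rotameric jumps) and slow microsecond-scale
## environment exchange.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

.checkStepValidity <- function(dMaxNsInv, deltaPs) {
  ## Gaussian increment model is valid for delta << 1/D; enforce the
  ## documented bound delta * 6 D < 0.01.
  if (deltaPs * 1e-3 * 6 * dMaxNsInv >= 0.01)
    stop("time step too coarse for the diffusion model: require ",
         "delta * 6 * D < 0.01 (got ", format(deltaPs * 1e-3 * 6 * dMaxNsInv),
         "); reduce deltaPs or the diffusion constant")
}

#' Construct a synthetic motion model
#'
#' Supported kinds and their parameters:
#' \describe{
#'   \item{`isotropic_diffusion`}{`tauRotNs` rank-2 correlation time
#'     (`D = 1/(6 tauRot)`).}
#'   \item{`axial_diffusion`}{`tauRotNs` (effective, from the mean diffusion
#'     constant) and `anisotropy` = D_par/D_perp about the body z axis.}
#'   \item{`cone_diffusion`}{`halfAngleDeg` cone half-angle about the
#'     molecular z axis and `dNsInv` wobble diffusion constant (1/ns).}
#'   \item{`discrete_jump`}{`sites` k x 4 matrix of site quaternions and
#'     `ratesPerUs` k x k rate matrix (off-diagonal rates, 1/us).}
#'   \item{`multistate_exchange`}{`models` list of sub-models (any
#'     diffusion/cone kind) and `ratesPerUs` switching-rate matrix; emulates
#'     microsecond-lifetime environment states.}
#' }
#'
#' @param kind Model kind string (see above).
#' @param ... Kind-specific parameters.
#' @param seed Integer seed recorded with the model; generation is exactly
#'   reproducible from (seed, parameters).
#' @return A [MotionModel-class].
#' @export
motionModel <- function(kind, ..., seed = 1L) {
  p <- list(...)
  m <- new("MotionModel", kind = kind, parameters = p,
           seed = as.integer(seed))
  switch(kind,
    isotropic_diffusion = {
      if (is.null(p$tauRotNs) || p$tauRotNs <= 0)
        stop("isotropic_diffusion requires tauRotNs > 0")
    },
    axial_diffusion = {
      if (is.null(p$tauRotNs) || p$tauRotNs <= 0)
        stop("axial_diffusion requires tauRotNs > 0")
      if (is.null(p$anisotropy) || p$anisotropy <= 0)
        stop("axial_diffusion requires anisotropy = Dpar/Dperp > 0")
    },
    cone_diffusion = {
      if (is.null(p$halfAngleDeg) || p$halfAngleDeg <= 0 ||
          p$halfAngleDeg > 180)
        stop("cone_diffusion requires halfAngleDeg in (0, 180]")
      if (is.null(p$dNsInv) || p$dNsInv <= 0)
        stop("cone_diffusion requires dNsInv > 0")
    },
    discrete_jump = {
      if (is.null(p$sites)) stop("discrete_jump requires site quaternions")
      sites <- .asQuatMatrix(p$sites)
      k <- nrow(sites)
      K <- p$ratesPerUs
      if (k > 1) {
        if (is.null(K) || !is.matrix(K) || any(dim(K) != k))
          stop("discrete_jump requires a k x k ratesPerUs matrix")
        .checkRateMatrix(K)
      }
    },
    multistate_exchange = {
      if (is.null(p$models) || !length(p$models))
        stop("multistate_exchange requires a list of sub-models")
      ok <- vapply(p$models, function(mm)
        is(mm, "MotionModel") && mm@kind != "multistate_exchange", logical(1))
      if (!all(ok))
        stop("sub-models must be MotionModel objects (not multistate)")
      .checkRateMatrix(p$ratesPerUs, length(p$models))
    },
    stop("unknown motion model kind: ", kind))
  m
}

.checkRateMatrix <- function(K, k = nrow(K)) {
  if (is.null(K) || !is.matrix(K) || any(dim(K) != k))
    stop("rate matrix must be k x k")
  off <- K; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal exchange rates must be non-negative")
  if (any(abs(rowSums(K)) > 1e-8 * max(abs(K), 1)))
    stop("rate matrix rows must sum to zero (non-stochastic rate matrix)")
  invisible(TRUE)
}

## Continuous-time Markov chain path on k states; returns per-frame state
## indices. Rates in 1/us, frames every deltaPs ps.
.markovPath <- function(K, nSteps, deltaPs, startState = 1L) {
  k <- nrow(K)
  if (k == 1L) return(rep(1L, nSteps))
  perPs <- K * 1e-6                       # 1/us -> 1/ps
  state <- integer(0)
  cur <- startState
  tEnd <- nSteps * deltaPs
  t <- 0
  while (t < tEnd) {
    exitRate <- -perPs[cur, cur]
    dwell <- if (exitRate > 0) stats::rexp(1, exitRate) else Inf
    nframes <- min(nSteps - length(state),
                   max(1L, ceiling(min(dwell, tEnd - t) / deltaPs)))
    state <- c(state, rep(cur, nframes))
    t <- length(state) * deltaPs
    if (length(state) >= nSteps) break
    w <- perPs[cur, ]; w[cur] <- 0
    cur <- sample.int(k, 1, prob = w)
  }
  state[seq_len(nSteps)]
}

## internal generators: all take a starting quaternion and a pre-seeded RNG
.generateDiffusion <- function(dAxesNsInv, nSteps, deltaPs, q0) {
  .checkStepValidity(max(dAxesNsInv), deltaPs)
  sd <- sqrt(2 * dAxesNsInv * deltaPs * 1e-3)    # rad, per body axis
  rv <- cbind(stats::rnorm(nSteps - 1, sd = sd[1]),
              stats::rnorm(nSteps - 1, sd = sd[2]),
              stats::rnorm(nSteps - 1, sd = sd[3]))
  .quatAccumulate(q0, quatFromAxisAngle(rv))
}

.generateCone <- function(dNsInv, halfAngleDeg, nSteps, deltaPs, q0) {
  .checkStepValidity(dNsInv, deltaPs)
  sd <- sqrt(2 * dNsInv * deltaPs * 1e-3)
  rv <- matrix(stats::rnorm(3 * (nSteps - 1), sd = sd), ncol = 3)
  cone_walk_cpp(q0, rv, cos(halfAngleDeg * pi / 180))
}

.generateJump <- function(sites, ratesPerUs, nSteps, deltaPs) {
  sites <- .asQuatMatrix(sites)
  if (nrow(sites) == 1L)
    return(sites[rep(1L, nSteps), , drop = FALSE])
  path <- .markovPath(ratesPerUs, nSteps, deltaPs)
  sites[path, , drop = FALSE]
}

.generateModelFrom <- function(model, nSteps, deltaPs, q0) {
  p <- model@parameters
  switch(model@kind,
    isotropic_diffusion = {
      D <- 1 / (6 * p$tauRotNs)
      .generateDiffusion(rep(D, 3), nSteps, deltaPs, q0)
    },
    axial_diffusion = {
      dMean <- 1 / (6 * p$tauRotNs)
      dPerp <- 3 * dMean / (p$anisotropy + 2)
      .generateDiffusion(c(dPerp, dPerp, p$anisotropy * dPerp),
                         nSteps, deltaPs, q0)
    },
    cone_diffusion =
      .generateCone(p$dNsInv, p$halfAngleDeg, nSteps, deltaPs, q0),
    discrete_jump =
      .generateJump(p$sites, p$ratesPerUs, nSteps, deltaPs),
    multistate_exchange = {
      path <- .markovPath(p$ratesPerUs, nSteps, deltaPs)
      q <- matrix(0, nSteps, 4)
      cur <- q0
      i <- 1L
      while (i <= nSteps) {
        j <- i
        while (j < nSteps && path[j + 1L] == path[i]) j <- j + 1L
        seg <- .generateModelFrom(p$models[[path[i]]], j - i + 1L,
                                  deltaPs, cur)
        q[i:j, ] <- seg[seq_len(j - i + 1L), , drop = FALSE]
        cur <- q[j, ]
        i <- j + 1L
      }
      q
    },
    stop("unknown motion model kind: ", model@kind))
}

#' Generate an orientational trajectory from a motion model
#'
#' @param model A [MotionModel-class].
#' @param nSteps Number of frames (>= 2).
#' @param deltaPs Time step, ps (default 1).
#' @param seed Optional seed overriding the model's recorded seed.
#' @return An [OrientationTrajectory-class].
#' @export
simulateMotion <- function(model, nSteps, deltaPs = 1, seed = NULL) {
  stopifnot(is(model, "MotionModel"), nSteps >= 2)
  if (is.null(seed)) seed <- model@seed
  q <- .withSeed(seed, .generateModelFrom(model, nSteps, deltaPs,
                                          c(1, 0, 0, 0)))
  orientationTrajectory(q[seq_len(nSteps), , drop = FALSE], deltaPs,
                        normalize = TRUE)
}

#' Brownian rotational diffusion trajectory
#'
#' Convenience wrapper around [simulateMotion()]: per step a small random
#' rotation with per-axis angular variance `2 D delta` is composed in the
#' molecular frame. For the isotropic model the rank-2 orientational
#' correlation time is `1/(6D) = tauRotNs`; with `anisotropy != 1` the body
#' z axis diffuses with `Dpar = anisotropy * Dperp` (mean fixed by
#' `tauRotNs`), emulating the modest axial anisotropy of globular-protein
#' tumbling.
#'
#' @param nSteps Number of frames.
#' @param tauRotNs Target rank-2 tumbling correlation time, ns.
#' @param deltaPs Step, ps.
#' @param anisotropy D_par/D_perp (1 = isotropic).
#' @param seed Integer seed.
#' @return An [OrientationTrajectory-class].
#' @export
brownianRotation <- function(nSteps, tauRotNs = 3.35, deltaPs = 1,
                             anisotropy = 1, seed = 1L) {
  kind <- if (anisotropy == 1) "isotropic_diffusion" else "axial_diffusion"
  m <- if (anisotropy == 1)
    motionModel(kind, tauRotNs = tauRotNs, seed = seed)
  else
    motionModel(kind, tauRotNs = tauRotNs, anisotropy = anisotropy,
                seed = seed)
  simulateMotion(m, nSteps, deltaPs)
}

#' Internal label motion trajectory
#'
#' Generates the PAS-to-molecule part of the label dynamics from a cone,
#' jump or multistate model (see [motionModel()]).
#'
#' @param model A [MotionModel-class].
#' @param nSteps Number of frames.
#' @param deltaPs Step, ps.
#' @return An [OrientationTrajectory-class].
#' @export
internalMotion <- function(model, nSteps, deltaPs = 1) {
  simulateMotion(model, nSteps, deltaPs)
}
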