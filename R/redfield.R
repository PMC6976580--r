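## Redfield-theory lineshape engine.
##
## The fluctuating rotating-frame Hamiltonian is H1(t) = Sz x dF(t) with
## dF(t) = dcg(t) 1 + dax(t) Ix + day(t) Iy + daz(t) Iz on the nuclear
## space (see secularCoefficients). Because H1 commutes with Sz, the
## relaxation superoperator does not mix electron coherence orders: the
## "Redfield kite" of this system consists of one exact block per electron
## coherence order, and the CW lineshape is governed entirely by the
## electron single-quantum block of dimension (2I+1)^2. On that block,
## restriction of the double-commutator master equation gives
##
##   dX/dt = -i(Hbar X + X Hbar) -
##     (1/4) sum_pq int_0^inf dtau C_pq(tau)
##       [ B_p Bq~L(tau) X + Bq~L(tau) X B_p
##       + B_p X Bq~R(tau) + X Bq~R(tau) B_p ]
##
## where Hbar = (1/2) sum_p cbar_p B_p, and the tilded operators carry the
## interaction-frame phases of the +/- electron manifolds. In the Hbar
## eigenbasis the time integrals reduce to one-sided spectral densities
## J_pq evaluated at the nuclear eigenfrequency differences. Cross terms
## between the Zeeman (p = 1) and hyperfine (p = 2..4) coefficients are the
## g x A cross-correlations; forcing them to zero symmetrises the doublet.

#' Trajectory correlation functions and spectral densities
#'
#' Computes lag-averaged auto- and cross-correlations of the four secular
#' coupling coefficients (anisotropic Zeeman shift and the laboratory-z
#' hyperfine components) along a trajectory, fits a single-exponential tail
#' for extrapolation beyond the sampled lag range, and records the
#' effective correlation time.
#'
#' @param traj An [OrientationTrajectory-class].
#' @param spec A [SpinSystem-class].
#' @param field A [FieldConfig-class].
#' @param maxLagPs Maximum sampled lag, ps (default: a tenth of the
#'   trajectory, capped at 50 ns). A warning is issued when the sampled
#'   range is not long relative to the recovered correlation time.
#' @param orientationGrid Number of uniformly distributed global rotations
#'   of the trajectory to average the correlations over (default 1); use
#'   the same grid here and in [brownianEnsembleFid()] when the Redfield
#'   prediction is to be compared with a direct-propagation ensemble, so
#'   that both engines see the same orientational statistics.
#' @param meanCoef Optional length-4 vector of mean secular coefficients
#'   (rad/s) imposed on the decomposition into static Hamiltonian and
#'   fluctuations, e.g. the exact ensemble mean of a larger direct run
#'   (from the FID `diagnostics` attribute). Default: the sample mean.
#' @return A [SpectralDensitySet-class].
#' @export
correlationFunctions <- function(traj, spec, field = fieldConfig(),
                                 maxLagPs = NULL, orientationGrid = 1L,
                                 meanCoef = NULL) {
  stopifnot(is(traj, "OrientationTrajectory"), is(spec, "SpinSystem"))
  delta <- trajectoryDelta(traj)
  n <- nFrames(traj)
  if (is.null(maxLagPs)) maxLagPs <- min(n * delta / 10, 5e4)
  L <- min(n - 2L, max(10L, floor(maxLagPs / delta)))
  grid <- if (orientationGrid > 1L)
    fibonacciOrientations(orientationGrid)
  else
    matrix(c(1, 0, 0, 0), 1)
  coefs <- lapply(seq_len(nrow(grid)), function(g)
    .secularCoefficientsQ(traj@quaternions, spec, field, qrot = grid[g, ]))
  mu <- if (is.null(meanCoef))
    colMeans(do.call(rbind, lapply(coefs, colMeans)))
  else
    as.numeric(meanCoef)
  corr <- array(0, c(4, 4, L + 1))
  for (coef in coefs)
    corr <- corr + .coefCorrelations(sweep(coef, 2, mu), L)
  corr <- corr / length(coefs)
  lag <- (0:L) * delta
  csum <- corr[1, 1, ] + corr[2, 2, ] + corr[3, 3, ] + corr[4, 4, ]
  c0 <- csum[1]
  rel <- csum / c0
  decays <- rel[L + 1] < 0.5
  if (!decays)
    warning("coupling correlation functions do not decay over the sampled ",
            "lag range; Redfield treatment is not valid for this trajectory")
  ## exponential tail from the late decay
  below <- which(rel < exp(-1))
  tauGuess <- if (length(below)) lag[below[1]] else lag[L + 1] / 2
  tailTau <- tryCatch({
    fitIdx <- which(rel > 0.01 & lag > tauGuess / 2)
    if (length(fitIdx) < 5) fitIdx <- seq_len(L + 1)
    lg <- lag[fitIdx]; rl <- rel[fitIdx]
    f <- minpack.lm::nlsLM(rl ~ a * exp(-lg / tau),
                           start = list(a = 1, tau = tauGuess),
                           lower = c(0, delta / 100))
    coef(f)[["tau"]]
  }, error = function(e) tauGuess)
  tauC <- sum(rel) * delta - delta / 2 + rel[L + 1] * tailTau
  if (lag[L + 1] < 10 * tauC)
    warning("sampled lag range (", lag[L + 1], " ps) is short relative to ",
            "the correlation time (", format(tauC), " ps)")
  new("SpectralDensitySet", lagPs = lag, corr = corr, meanCoef = mu,
      tailTauPs = tailTau, tailAmp = corr[, , L + 1],
      tauCPs = tauC, decays = decays)
}

#' Evaluate the one-sided spectral-density matrix
#'
#' `J_pq(w) = int_0^inf C_pq(tau) exp(-i w tau) dtau`, computed by
#' trapezoidal quadrature of the sampled correlations plus the analytic
#' transform of the fitted exponential tail. The real part drives
#' relaxation; the imaginary part carries the dynamic frequency shifts.
#'
#' @param sd A [SpectralDensitySet-class].
#' @param omega Angular frequency, rad/s (scalar).
#' @return 4 x 4 complex matrix.
#' @export
spectralDensityMatrix <- function(sd, omega) {
  stopifnot(is(sd, "SpectralDensitySet"))
  tau <- sd@lagPs * 1e-12
  dt <- tau[2] - tau[1]
  ph <- exp(-1i * omega * tau)
  w <- rep(dt, length(tau)); w[1] <- dt / 2; w[length(tau)] <- dt / 2
  J <- matrix(0i, 4, 4)
  for (p in 1:4) for (q in 1:4)
    J[p, q] <- sum(sd@corr[p, q, ] * ph * w)
  if (is.finite(sd@tailTauPs) && sd@decays) {
    tt <- sd@tailTauPs * 1e-12
    Tend <- tau[length(tau)]
    J <- J + sd@tailAmp * exp(-1i * omega * Tend) * tt / (1 + 1i * omega * tt)
  }
  J
}

#' Assemble the Redfield model for the electron single-quantum block
#'
#' Builds the coherent Liouvillian from the motionally averaged Hamiltonian
#' and the relaxation supermatrix from the trajectory spectral densities,
#' in the eigenbasis of the averaged nuclear Hamiltonian. With
#' `includeCrossCorrelations = FALSE` every term mixing the anisotropic
#' Zeeman coefficient with the hyperfine coefficients is forced to zero,
#' which renders the predicted doublet of a 15N system symmetric.
#'
#' @param sd A [SpectralDensitySet-class] from [correlationFunctions()].
#' @param spec A [SpinSystem-class].
#' @param includeCrossCorrelations Keep g x A cross terms (default TRUE).
#' @param dynamicShifts Keep imaginary parts of J (default TRUE).
#' @return A [RedfieldModel-class].
#' @export
buildRedfield <- function(sd, spec, includeCrossCorrelations = TRUE,
                          dynamicShifts = TRUE) {
  stopifnot(is(sd, "SpectralDensitySet"), is(spec, "SpinSystem"))
  if (!sd@decays)
    stop("correlation functions do not decay; Redfield theory is invalid ",
         "for this trajectory")
  I <- .angularMomentum(spec@nuclearSpin)
  dI <- nrow(I$Jz)
  B <- list(diag(dI) + 0i, I$Jx, I$Jy, I$Jz)
  Hbar <- matrix(0i, dI, dI)
  for (p in 1:4) Hbar <- Hbar + 0.5 * sd@meanCoef[p] * B[[p]]
  e <- eigen(Hbar, symmetric = TRUE)
  V <- e$vectors; eps <- e$values
  Bt <- lapply(B, function(b) Conj(t(V)) %*% b %*% V)
  mask <- matrix(1, 4, 4)
  if (!includeCrossCorrelations) {
    mask[1, 2:4] <- 0
    mask[2:4, 1] <- 0
  }
  ## spectral densities at all +/- eigenfrequency differences
  dEps <- outer(eps, eps, "-")
  omegas <- unique(as.vector(c(dEps, -dEps)))
  Jcache <- lapply(omegas, function(om) {
    J <- spectralDensityMatrix(sd, om) * mask
    if (!dynamicShifts) J <- Re(J) + 0i
    J
  })
  idxPos <- matrix(match(as.vector(dEps), omegas), dI, dI)
  idxNeg <- matrix(match(as.vector(-dEps), omegas), dI, dI)
  Id <- diag(dI) + 0i
  R <- matrix(0i, dI^2, dI^2)
  for (p in 1:4) for (q in 1:4) {
    JL <- matrix(0i, dI, dI); JR <- matrix(0i, dI, dI)
    for (m in 1:dI) for (n2 in 1:dI) {
      JL[m, n2] <- Jcache[[idxPos[m, n2]]][p, q] * Bt[[q]][m, n2]
      JR[m, n2] <- Jcache[[idxNeg[m, n2]]][p, q] * Bt[[q]][m, n2]
    }
    R <- R + 0.25 * (kronecker(Id, Bt[[p]] %*% JL) +
                     kronecker(t(Bt[[p]]), JL) +
                     kronecker(t(JR), Bt[[p]]) +
                     kronecker(t(JR %*% Bt[[p]]), Id))
  }
  Hd <- diag(eps) + 0i
  L <- -1i * (kronecker(Id, Hd) + kronecker(t(Hd), Id)) - R
  lam <- eigen(L, only.values = TRUE)$values
  maxRate <- max(-Re(lam))
  if (max(Re(lam)) > 1e-10 * max(maxRate, 1))
    warning("relaxation supermatrix has growing eigenmodes (max Re = ",
            format(max(Re(lam))), "); the Redfield model may be unphysical")
  new("RedfieldModel", liouvillian = L, dimension = as.integer(dI),
      spec = spec, includeCrossCorrelations = includeCrossCorrelations,
      detect = as.complex(as.vector(Id)),
      start = as.complex(as.vector(Id / 2)))
}

## eigen decomposition of the Liouvillian into detectable modes:
## FID(tau) = sum_k conj(c_k) exp(conj(lambda_k) tau)
.redfieldModes <- function(model) {
  L <- model@liouvillian
  e <- eigen(L)
  W <- e$vectors
  kap <- tryCatch(kappa(W, exact = FALSE), error = function(err) Inf)
  if (!is.finite(kap) || kap > 1e12)
    warning("Liouvillian eigenvector matrix is ill-conditioned (near ",
            "defective); mode amplitudes may be inaccurate")
  a <- solve(W, model@start)
  d <- as.vector(Conj(model@detect) %*% W)
  list(lambda = e$values, weight = d * a)
}

#' Redfield-predicted FID
#'
#' Synthesises the detected transverse-magnetisation decay from the
#' eigenmodes of the single-quantum Liouvillian on an arbitrary uniform
#' time grid, so that the Redfield prediction can be pushed through exactly
#' the same broadening/modulation post-processing as the direct-propagation
#' result.
#'
#' @param model A [RedfieldModel-class].
#' @param timesPs Uniform time axis, ps.
#' @return A [Fid-class].
#' @export
redfieldFid <- function(model, timesPs) {
  stopifnot(is(model, "RedfieldModel"))
  md <- .redfieldModes(model)
  tS <- timesPs * 1e-12
  vals <- complex(length(tS))
  for (k in seq_along(md$lambda))
    vals <- vals + Conj(md$weight[k]) * exp(Conj(md$lambda[k]) * tS)
  new("Fid", timesPs = timesPs, values = vals, carrier = "rotating frame")
}

#' Eigenmode table of a Redfield model
#'
#' Per detectable eigenmode: decay rate (1/s), offset frequency (rad/s, in
#' the detected-FID convention) and complex weight. Fast-motion 14N models
#' reduce to three dominant modes whose rates follow the motional-narrowing
#' pattern `A + B mI + C mI^2`.
#'
#' @param model A [RedfieldModel-class].
#' @return `data.frame` with columns `rate`, `frequency`, `weight`
#'   (complex), ordered by decreasing |weight|.
#' @export
redfieldLinewidths <- function(model) {
  md <- .redfieldModes(model)
  out <- data.frame(rate = -Re(md$lambda),
                    frequency = -Im(md$lambda),
                    weightRe = Re(md$weight), weightIm = Im(md$weight))
  out[order(-abs(complex(real = out$weightRe, imaginary = out$weightIm))), ]
}

#' Redfield-theory CW spectrum
#'
#' Generates the Redfield FID and applies the same broadening, modulation
#' and field-axis mapping as the direct-propagation pipeline.
#'
#' @param model A [RedfieldModel-class].
#' @param broadening A [BroadeningModel-class].
#' @param modulation A [ModulationConfig-class] (ignored in absorption
#'   mode).
#' @param mode `"first_derivative"` or `"absorption"`.
#' @param fidLength,dtPs FID sampling (defaults 8192 points every 64 ps).
#' @param sweepMt,nPoints Field axis.
#' @return An [EsrSpectrum-class].
#' @export
redfieldSpectrum <- function(model, broadening = broadeningModel(),
                             modulation = modulationConfig(),
                             mode = c("first_derivative", "absorption"),
                             fidLength = 8192, dtPs = 64, sweepMt = 12,
                             nPoints = 2048) {
  mode <- match.arg(mode)
  fid <- redfieldFid(model, (seq_len(fidLength) - 1) * dtPs)
  fid <- applyBroadening(fid, broadening)
  sp <- if (mode == "first_derivative")
    modulatedSpectrum(fid, model@spec, modulation, sweepMt, nPoints)
  else
    absorptionSpectrum(fid, model@spec, sweepMt, nPoints)
  sp <- gaussianConvolve(sp, broadening@gaussianFwhmUt)
  sp@meta <- c(sp@meta,
               list(engine = "redfield",
                    crossCorrelations = model@includeCrossCorrelations))
  sp
}

#' One-call Redfield simulation from a trajectory
#'
#' @inheritParams correlationFunctions
#' @inheritParams redfieldSpectrum
#' @param includeCrossCorrelations Keep g x A cross-correlation terms.
#' @return An [EsrSpectrum-class].
#' @export
simulateRedfield <- function(traj, spec, field = fieldConfig(),
                             maxLagPs = NULL,
                             includeCrossCorrelations = TRUE,
                             broadening = broadeningModel(),
                             modulation = modulationConfig(),
                             mode = c("first_derivative", "absorption"),
                             fidLength = 8192, dtPs = 64, sweepMt = 12,
                             nPoints = 2048) {
  sd <- correlationFunctions(traj, spec, field, maxLagPs)
  model <- buildRedfield(sd, spec, includeCrossCorrelations)
  redfieldSpectrum(model, broadening, modulation, match.arg(mode),
                   fidLength, dtPs, sweepMt, nPoints)
}

#' Redfield validity report
#'
#' Compares the coupling correlation time tau_c with the electron coherence
#' lifetime T2e (Redfield validity requires tau_c << T2e). T2e is reported
#' both as the slowest detectable eigenmode decay time and as the 1/e time
#' of the predicted FID envelope; the verdict tiers are valid
#' (ratio < 0.05), marginal (< 0.2) and invalid.
#'
#' @inheritParams correlationFunctions
#' @return List with `tauCNs`, `t2eNs` (slowest eigenmode), `t2eFidNs`
#'   (FID 1/e), `ratio` and `verdict`.
#' @export
validityReport <- function(traj, spec, field = fieldConfig(),
                           maxLagPs = NULL) {
  sd <- correlationFunctions(traj, spec, field, maxLagPs)
  if (!sd@decays)
    return(list(tauCNs = Inf, t2eNs = NA_real_, t2eFidNs = NA_real_,
                ratio = Inf, verdict = "invalid"))
  model <- buildRedfield(sd, spec)
  md <- .redfieldModes(model)
  wMag <- abs(md$weight)
  keep <- wMag > 1e-3 * max(wMag)
  t2e <- 1 / min(-Re(md$lambda[keep]))
  tPs <- seq(0, 5 * t2e * 1e12, length.out = 4096)
  fid <- redfieldFid(model, tPs)
  env <- Mod(fid@values) / Mod(fid@values[1])
  idx <- which(env < exp(-1))
  t2eFid <- if (length(idx)) tPs[idx[1]] * 1e-12 else NA_real_
  tauC <- sd@tauCPs * 1e-12
  ratio <- tauC / t2e
  verdict <- if (ratio < 0.05) "valid" else if (ratio < 0.2) "marginal"
             else "invalid"
  list(tauCNs = tauC * 1e9, t2eNs = t2e * 1e9, t2eFidNs = t2eFid * 1e9,
       ratio = ratio, verdict = verdict)
}
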