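## Exact lineshape engine: per-frame propagators, windowed density-matrix
## evolution, FID detection, extra broadening, and the modulation-detected
## first-derivative spectrum.

#' Elementary propagators along a trajectory
#'
#' `U_k = exp(i H(t_k) delta)` for every frame, computed exactly by
#' eigendecomposition of the Hermitian rotating-frame Hamiltonian. Intended
#' for inspection and testing; the production FID engine composes the same
#' propagators in compiled code without materialising them.
#'
#' @param traj An [OrientationTrajectory-class].
#' @param spec A [SpinSystem-class].
#' @param field A [FieldConfig-class].
#' @return List of unitary complex matrices, one per frame.
#' @export
propagatorSequence <- function(traj, spec, field = fieldConfig()) {
  stopifnot(is(traj, "OrientationTrajectory"))
  deltaS <- trajectoryDelta(traj) * 1e-12
  q <- trajectoryQuaternions(traj)
  lapply(seq_len(nrow(q)), function(k) {
    H <- spinHamiltonian(spec, q[k, ], field, frame = "rotating")
    e <- eigen(H, symmetric = TRUE)
    e$vectors %*% diag(exp(1i * e$values * deltaS)) %*% Conj(t(e$vectors))
  })
}

#' Compute the ensemble-averaged free induction decay
#'
#' Implements the direct propagation scheme: starting from
#' `sigma(0) = Sx`, the density matrix is evolved through the elementary
#' propagators of consecutive trajectory frames and the transverse
#' magnetisation `Tr{S+ sigma(tau)}` is recorded. The trajectory average is
#' realised by repeating the evolution from start frames spaced `stridePs`
#' apart and averaging the detected FIDs.
#'
#' The FID is detected in the frame rotating at the isotropic electron
#' Zeeman frequency and recorded every `decimation` trajectory steps;
#' the resulting sampling rate must cover the spectral width of interest
#' (validated against `sweepMt`).
#'
#' @param traj An [OrientationTrajectory-class].
#' @param spec A [SpinSystem-class].
#' @param field A [FieldConfig-class].
#' @param fidLength Number of recorded FID points (default 8192).
#' @param decimation Recording interval in trajectory steps (default 64,
#'   i.e. 64 ps at the 1 ps MD step).
#' @param stridePs Window stride in ps (default 1000 = 1 ns).
#' @param sweepMt Sweep width (mT) the FID must support, for the Nyquist
#'   check (default 12).
#' @param engine `"compiled"` (default) or `"reference"` (pure R full-matrix
#'   evolution with explicit Hermiticity/trace checks; small inputs only).
#' @return A [Fid-class]; attribute `"diagnostics"` carries the maximum
#'   propagator-unitarity deviation and the number of windows averaged.
#' @export
computeFid <- function(traj, spec, field = fieldConfig(),
                       fidLength = 8192, decimation = 64,
                       stridePs = 1000, sweepMt = 12,
                       engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  stopifnot(is(traj, "OrientationTrajectory"), is(spec, "SpinSystem"))
  delta <- trajectoryDelta(traj)
  n <- nFrames(traj)
  winLen <- fidLength * decimation
  if (winLen > n)
    stop("FID window (", winLen, " frames) exceeds the trajectory (",
         n, " frames); reduce fidLength or decimation")
  ## Nyquist: sampling rate must cover the half sweep as offset frequency
  fs <- 1 / (decimation * delta * 1e-12)
  fmax <- fieldToAngularFrequency(sweepMt * 1e-3 / 2, gIso(spec)) / (2 * pi)
  if (fs < 2 * fmax)
    stop("decimation too coarse: FID sampling rate ", format(fs / 1e6),
         " MHz cannot represent the ", sweepMt, " mT sweep (needs >= ",
         format(2 * fmax / 1e6), " MHz)")
  strideFrames <- max(1L, round(stridePs / delta))
  starts <- seq.int(0L, n - winLen, by = strideFrames)
  coef <- secularCoefficients(traj, spec, field)
  if (engine == "compiled") {
    res <- fid_engine_cpp(coef, delta * 1e-12, 2L * spec@nuclearSpin + 1L,
                          as.integer(fidLength), as.integer(decimation),
                          as.integer(starts))
  } else {
    res <- .fidReference(coef, delta * 1e-12, spec, fidLength, decimation,
                         starts)
  }
  fid <- new("Fid", timesPs = (seq_len(fidLength) - 1) * delta * decimation,
             values = as.complex(res$fid), carrier = "rotating frame")
  attr(fid, "diagnostics") <- list(maxUnitarityDev = res$maxUnitarityDev,
                                   nWindows = res$nWindows,
                                   maxHermitianDev = res$maxHermitianDev,
                                   maxTraceDev = res$maxTraceDev)
  fid
}

## Reference implementation: full-matrix sigma evolution with invariant
## checks (Hermiticity and trace conservation every 1000 steps, 1e-9).
.fidReference <- function(coef, deltaS, spec, fidLength, decimation, starts) {
  ops <- spinOperators(spec@nuclearSpin)@operators
  d <- nrow(ops$Sx)
  fid <- complex(fidLength)
  maxHerm <- 0; maxTrace <- 0; maxU <- 0
  for (s0 in starts) {
    sigma <- ops$Sx
    G <- diag(d) + 0i
    rec <- 1L
    fid[rec] <- fid[rec] + sum(diag(ops$Sp %*% sigma))
    for (k in seq_len(fidLength * decimation)) {
      t <- s0 + k
      H <- coef[t, 1] * ops$Sz +
        ops$Sz %*% (coef[t, 2] * ops$Ix + coef[t, 3] * ops$Iy +
                    coef[t, 4] * ops$Iz)
      e <- eigen(H, symmetric = TRUE)
      U <- e$vectors %*% (exp(1i * e$values * deltaS) * Conj(t(e$vectors)))
      maxU <- max(maxU, max(Mod(Conj(t(U)) %*% U - diag(d))))
      G <- G %*% U
      if (k %% 1000 == 0 || k == fidLength * decimation) {
        sigma <- Conj(t(G)) %*% ops$Sx %*% G
        maxHerm <- max(maxHerm, max(Mod(sigma - Conj(t(sigma)))))
        maxTrace <- max(maxTrace, Mod(sum(diag(sigma)) - sum(diag(ops$Sx))))
      }
      if (k %% decimation == 0 && rec < fidLength) {
        rec <- rec + 1L
        sig <- Conj(t(G)) %*% ops$Sx %*% G
        fid[rec] <- fid[rec] + sum(diag(ops$Sp %*% sig))
      }
    }
  }
  list(fid = fid / length(starts), maxUnitarityDev = maxU,
       nWindows = length(starts), maxHermitianDev = maxHerm,
       maxTraceDev = maxTrace)
}

#' Apply the oxygen and inhomogeneity broadening model to an FID
#'
#' Multiplies the FID by `exp(-tau / T2O2)` (homogeneous Lorentzian term
#' from collisions with dissolved paramagnetic oxygen). The Gaussian
#' inhomogeneity term acts on the synthesised spectrum; see
#' [gaussianConvolve()].
#'
#' @param fid A [Fid-class].
#' @param model A [BroadeningModel-class].
#' @return The broadened [Fid-class].
#' @export
applyBroadening <- function(fid, model) {
  stopifnot(is(fid, "Fid"), is(model, "BroadeningModel"))
  if (is.finite(model@t2O2Us)) {
    dg <- attr(fid, "diagnostics")
    fid@values <- fid@values * exp(-fid@timesPs / (model@t2O2Us * 1e6))
    attr(fid, "diagnostics") <- dg
  }
  fid
}

#' Convolve a spectrum with a unit-area Gaussian
#'
#' Models static-field inhomogeneity and unresolved hyperfine couplings as
#' a Gaussian contour of given full width at half height on the field axis.
#'
#' @param spectrum An [EsrSpectrum-class] on a uniform field axis.
#' @param fwhmUt Gaussian FWHH in microtesla (0 returns the input).
#' @return The convolved [EsrSpectrum-class].
#' @export
gaussianConvolve <- function(spectrum, fwhmUt) {
  stopifnot(is(spectrum, "EsrSpectrum"))
  if (fwhmUt <= 0) return(spectrum)
  x <- spectrum@fieldMt
  dB <- diff(x[1:2])
  sigma <- fwhmUt * 1e-3 / (2 * sqrt(2 * log(2)))   # mT
  half <- max(1L, ceiling(4 * sigma / dB))
  k <- stats::dnorm(seq(-half, half) * dB, sd = sigma) * dB
  k <- k / sum(k)
  y <- stats::convolve(spectrum@intensity, rev(k), type = "open")
  spectrum@intensity <- y[(half + 1):(half + length(x))]
  spectrum
}

## One-sided Fourier transform of the FID evaluated on a uniform field
## axis; returns list(fieldMt, transform (complex)).
.fidTransform <- function(values, timesPs, gIso, sweepMt, nPoints, pad = 8) {
  dt <- diff(timesPs[1:2]) * 1e-12
  n <- length(values)
  L <- stats::nextn(pad * n, 2)
  ## trapezoid end-point correction for the one-sided integral
  v <- c(values, complex(L - n))
  v[1] <- v[1] / 2
  ft <- stats::fft(v) * dt
  freq <- c(seq(0, L / 2 - 1), seq(-L / 2, -1)) / (L * dt)  # Hz
  omega <- 2 * pi * freq
  fieldMt <- -angularFrequencyToField(omega, gIso) * 1e3
  ord <- order(fieldMt)
  axis <- seq(-sweepMt / 2, sweepMt / 2, length.out = nPoints)
  re <- stats::approx(fieldMt[ord], Re(ft)[ord], xout = axis)$y
  im <- stats::approx(fieldMt[ord], Im(ft)[ord], xout = axis)$y
  list(fieldMt = axis, transform = complex(real = re, imaginary = im))
}

#' Absorption-mode spectrum from an FID
#'
#' Real part of the one-sided Fourier transform of the (broadened) FID,
#' mapped to the field axis through `dB = -hbar dw / (gIso muB)` so that a
#' positive isotropic hyperfine coupling puts the mI = -1 line at high
#' field.
#'
#' @param fid A [Fid-class].
#' @param spec A [SpinSystem-class] (supplies gIso for the field mapping).
#' @param sweepMt Sweep width in mT (axis spans +/- sweepMt/2).
#' @param nPoints Number of field-axis points.
#' @return An [EsrSpectrum-class] with `mode = "absorption"`.
#' @export
absorptionSpectrum <- function(fid, spec, sweepMt = 12, nPoints = 2048) {
  stopifnot(is(fid, "Fid"))
  g <- gIso(spec)
  tr <- .fidTransform(fid@values, fid@timesPs, g, sweepMt, nPoints)
  esrSpectrum(tr$fieldMt, Re(tr$transform), mode = "absorption",
              meta = list(gIso = g, sweepMt = sweepMt))
}

#' Modulation-detected first-derivative spectrum from an FID
#'
#' Emulates field modulation followed by phase-sensitive detection:
#' `s(w) = -Im integral FID(tau) J1(Hm tau / 2) exp(-i w tau) dtau`,
#' with `J1` the Bessel function of the first kind of order 1 and `Hm` the
#' peak-to-peak modulation amplitude converted to rad/s via
#' `gIso muB / hbar`. In the small-modulation regime this reduces to the
#' first derivative of the absorption lineshape scaled by `Hm/4`.
#'
#' @param fid A [Fid-class] (should have decayed below 1 percent of its
#'   initial value; a truncation warning is issued otherwise).
#' @param spec A [SpinSystem-class].
#' @param modulation A [ModulationConfig-class] (default 0.05 mT).
#' @param sweepMt Sweep width in mT.
#' @param nPoints Number of field-axis points.
#' @return An [EsrSpectrum-class] with `mode = "first_derivative"`.
#' @export
modulatedSpectrum <- function(fid, spec, modulation = modulationConfig(),
                              sweepMt = 12, nPoints = 2048) {
  stopifnot(is(fid, "Fid"), is(modulation, "ModulationConfig"))
  g <- gIso(spec)
  endFrac <- Mod(fid@values[length(fid@values)]) / max(Mod(fid@values[1]), .Machine$double.eps)
  if (is.finite(endFrac) && endFrac > 0.01)
    warning("FID has decayed to only ", format(100 * endFrac, digits = 3),
            " percent of its initial value; expect truncation ringing")
  hmRad <- fieldToAngularFrequency(modulation@hmMt * 1e-3, g)
  tauS <- fid@timesPs * 1e-12
  weighted <- fid@values * besselJ(hmRad * tauS / 2, nu = 1)
  tr <- .fidTransform(weighted, fid@timesPs, g, sweepMt, nPoints)
  esrSpectrum(tr$fieldMt, -Im(tr$transform), mode = "first_derivative",
              meta = list(gIso = g, sweepMt = sweepMt,
                          hmMt = modulation@hmMt))
}

#' One-call direct-propagation simulation of a CW ESR spectrum
#'
#' Chains [computeFid()], [applyBroadening()], spectrum synthesis and
#' [gaussianConvolve()] into the standard pipeline.
#'
#' @inheritParams computeFid
#' @param broadening A [BroadeningModel-class] (default: air-equilibrated
#'   aqueous values, T2O2 = 0.83 us and 126 uT Gaussian).
#' @param modulation A [ModulationConfig-class] or `NULL` for absorption
#'   mode.
#' @param mode `"first_derivative"` (default) or `"absorption"`.
#' @param nPoints Field-axis points.
#' @return An [EsrSpectrum-class].
#' @export
simulateDirect <- function(traj, spec, field = fieldConfig(),
                           broadening = broadeningModel(),
                           modulation = modulationConfig(),
                           mode = c("first_derivative", "absorption"),
                           fidLength = 8192, decimation = 64,
                           stridePs = 1000, sweepMt = 12, nPoints = 2048) {
  mode <- match.arg(mode)
  fid <- computeFid(traj, spec, field, fidLength = fidLength,
                    decimation = decimation, stridePs = stridePs,
                    sweepMt = sweepMt)
  fid <- applyBroadening(fid, broadening)
  sp <- if (mode == "first_derivative")
    modulatedSpectrum(fid, spec, modulation, sweepMt, nPoints)
  else
    absorptionSpectrum(fid, spec, sweepMt, nPoints)
  sp <- gaussianConvolve(sp, broadening@gaussianFwhmUt)
  sp@meta <- c(sp@meta, list(t2O2Us = broadening@t2O2Us,
                             gaussianFwhmUt = broadening@gaussianFwhmUt,
                             B0 = field@B0))
  sp
}

#' Ensemble-averaged FID for Brownian tumbling, streamed in chunks
#'
#' The windowed FID average converges with the number of statistically
#' independent windows, so fast-motion systems (long FIDs, slow phase
#' accumulation) need trajectories of tens of microseconds. This driver
#' generates an isotropic Brownian rotational-diffusion trajectory in
#' memory-bounded chunks (the quaternion is carried across chunk
#' boundaries, so the path is one continuous realisation), runs the
#' propagation engine on each chunk and accumulates the window-averaged
#' FID.
#'
#' @param spec A [SpinSystem-class].
#' @param field A [FieldConfig-class].
#' @param tauRotNs Rank-2 rotational correlation time of the generator, ns.
#' @param nSteps Total trajectory length in frames.
#' @param deltaPs Elementary step, ps (default 1).
#' @param seed Integer seed (the realisation is reproducible from the seed
#'   and the chunk size).
#' @param fidLength,decimation FID sampling (see [computeFid()]).
#' @param strideFrames Window stride in frames (default: half a window).
#' @param chunkFrames Frames generated and propagated per chunk
#'   (default 4e6); windows do not span chunk boundaries.
#' @param orientationGrid Number of uniformly distributed global rotations
#'   of the trajectory to average over (default 1). Because the secular
#'   coefficients depend only on the laboratory z direction, a Fibonacci
#'   grid of field directions completes the powder average and sharply
#'   reduces the Monte-Carlo variance of the windowed FID estimate.
#' @return A [Fid-class] with window-count diagnostics.
#' @export
brownianEnsembleFid <- function(spec, field = fieldConfig(), tauRotNs,
                                nSteps, deltaPs = 1, seed = 1L,
                                fidLength = 8192, decimation = 64,
                                strideFrames = NULL, chunkFrames = 4e6,
                                orientationGrid = 1L) {
  winLen <- fidLength * decimation
  if (is.null(strideFrames)) strideFrames <- winLen %/% 2L
  chunkFrames <- max(chunkFrames, winLen + 1)
  D <- 1 / (6 * tauRotNs)
  grid <- if (orientationGrid > 1L)
    fibonacciOrientations(orientationGrid)
  else
    matrix(c(1, 0, 0, 0), 1)
  acc <- complex(fidLength)
  totWin <- 0L
  maxU <- 0
  meanAcc <- numeric(4)
  meanN <- 0
  .withSeed(seed, {
    q0 <- c(1, 0, 0, 0)
    done <- 0
    carry <- 0L   # frames of stride offset carried across chunks
    while (done < nSteps) {
      n <- min(chunkFrames, nSteps - done)
      if (n < 2) break
      q <- .generateDiffusion(rep(D, 3), n, deltaPs, q0)[seq_len(n), ,
                                                         drop = FALSE]
      q0 <- q[n, ]
      done <- done + n
      if (n >= winLen + 1) {
        starts <- seq.int(carry, n - winLen - 1L, by = strideFrames)
        carry <- (max(starts) + strideFrames) - (n - winLen - 1L)
        carry <- max(0L, min(carry, strideFrames - 1L))
        for (g in seq_len(nrow(grid))) {
          coef <- .secularCoefficientsQ(q, spec, field, qrot = grid[g, ])
          res <- fid_engine_cpp(coef, deltaPs * 1e-12,
                                2L * spec@nuclearSpin + 1L,
                                as.integer(fidLength),
                                as.integer(decimation),
                                as.integer(starts))
          acc <- acc + as.complex(res$fid) * length(starts)
          totWin <- totWin + length(starts)
          maxU <- max(maxU, res$maxUnitarityDev)
          meanAcc <- meanAcc + colSums(coef)
          meanN <- meanN + nrow(coef)
        }
      }
    }
  })
  if (totWin == 0L) stop("trajectory too short for a single FID window")
  fid <- new("Fid",
             timesPs = (seq_len(fidLength) - 1) * deltaPs * decimation,
             values = acc / totWin, carrier = "rotating frame")
  attr(fid, "diagnostics") <- list(maxUnitarityDev = maxU,
                                   nWindows = totWin,
                                   meanCoef = meanAcc / meanN)
  fid
}

#' Uniformly distributed frozen orientations
#'
#' Fibonacci-sphere grid of laboratory field directions, returned as
#' PAS-to-lab quaternions; used for rigid-limit (powder) ensembles.
#'
#' @param n Number of orientations.
#' @return `n x 4` matrix of unit quaternions.
#' @export
fibonacciOrientations <- function(n) {
  i <- seq_len(n) - 0.5
  zc <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  v <- cbind(sqrt(1 - zc^2) * cos(phi), sqrt(1 - zc^2) * sin(phi), zc)
  q <- matrix(0, n, 4)
  for (k in seq_len(n)) {
    ## rotation taking PAS vector v to the lab z axis applied inversely:
    ## choose R with third row = v so that lab z resolves to v in the PAS
    zAxis <- v[k, ]
    ref <- if (abs(zAxis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    xAxis <- pracma::cross(ref, zAxis)
    xAxis <- xAxis / sqrt(sum(xAxis^2))
    yAxis <- pracma::cross(zAxis, xAxis)
    q[k, ] <- quatFromMatrix(rbind(xAxis, yAxis, zAxis))
  }
  q
}

#' Rigid-limit (powder) FID by direct propagation
#'
#' Evolves the frozen-orientation ensemble over a uniform orientation grid
#' with the same propagation engine used for dynamic trajectories and
#' averages the detected FIDs.
#'
#' @param spec A [SpinSystem-class].
#' @param field A [FieldConfig-class].
#' @param nOrientations Grid size (default 256).
#' @param fidLength,decimation FID sampling (defaults 4096 points, 32 steps).
#' @param deltaPs Elementary step, ps.
#' @return A [Fid-class] of the powder ensemble.
#' @export
rigidLimitFid <- function(spec, field = fieldConfig(), nOrientations = 256,
                          fidLength = 4096, decimation = 32, deltaPs = 1) {
  q <- fibonacciOrientations(nOrientations)
  winLen <- fidLength * decimation
  acc <- complex(fidLength)
  dg <- 0
  for (k in seq_len(nOrientations)) {
    traj <- orientationTrajectory(q[rep(k, 2), , drop = FALSE], deltaPs)
    coef <- secularCoefficients(traj, spec, field)
    coef <- coef[rep(1L, winLen + 1L), , drop = FALSE]
    res <- fid_engine_cpp(coef, deltaPs * 1e-12,
                          2L * spec@nuclearSpin + 1L,
                          as.integer(fidLength), as.integer(decimation),
                          as.integer(0))
    acc <- acc + as.complex(res$fid)
    dg <- max(dg, res$maxUnitarityDev)
  }
  fid <- new("Fid", timesPs = (seq_len(fidLength) - 1) * deltaPs * decimation,
             values = acc / nOrientations, carrier = "rotating frame")
  attr(fid, "diagnostics") <- list(maxUnitarityDev = dg,
                                   nWindows = nOrientations)
  fid
}
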