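## a spin system with no couplings at all: H_rot = 0
specNull <- spinSystem(1, gPrincipal = rep(2.0059, 3),
                       aPrincipal = rep(0, 3))
## isotropic hyperfine only
specIsoA <- spinSystem(1, gPrincipal = rep(2.0059, 3),
                       aPrincipal = rep(44, 3))

test_that("propagators are unitary and reduce to identity for H = 0", {
  traj <- orientationTrajectory(randomQuats(5, seed = 41), 1,
                                normalize = TRUE)
  U0 <- propagatorSequence(traj, specNull, fieldX)
  for (U in U0) expect_equal(U, diag(6) + 0i, tolerance = 1e-12)
  U <- propagatorSequence(traj, specN14, fieldX)
  for (u in U)
    expect_lt(max(Mod(Conj(t(u)) %*% u - diag(6))), 1e-10)
})

test_that("accumulated static propagators equal the matrix exponential", {
  q <- randomQuats(1, seed = 42)[1, ]
  traj <- orientationTrajectory(matrix(rep(q, 10), ncol = 4, byrow = TRUE),
                                1)
  U <- propagatorSequence(traj, specN14, fieldX)
  acc <- Reduce(`%*%`, U)
  H <- spinHamiltonian(specN14, q, fieldX)
  expect_equal(acc, expmHermitian(H, 10e-12), tolerance = 1e-9)
})

test_that("FID for H = 0 is constant at Tr(S+ Sx) = (2I+1)/2", {
  traj <- orientationTrajectory(randomQuats(3000, seed = 43), 1,
                                normalize = TRUE)
  fid <- computeFid(traj, specNull, fieldX, fidLength = 32,
                    decimation = 16, stridePs = 2000)
  expect_equal(fidValues(fid), rep(1.5 + 0i, 32), tolerance = 1e-12)
})

test_that("isotropic-only Hamiltonian gives three equal-weight lines", {
  traj <- orientationTrajectory(randomQuats(3000, seed = 44), 1,
                                normalize = TRUE)
  fid <- computeFid(traj, specIsoA, fieldX, fidLength = 64,
                    decimation = 16, stridePs = 2000)
  aRad <- 44e6 * 2 * pi
  t <- fidTimes(fid) * 1e-12
  analytic <- 0.5 * (1 + 2 * cos(aRad * t))
  expect_equal(fidValues(fid), as.complex(analytic), tolerance = 1e-8)
})

test_that("a single static orientation oscillates at the stick positions", {
  q <- randomQuats(1, seed = 45)[1, ]
  traj <- orientationTrajectory(matrix(rep(q, 2100), ncol = 4, byrow = TRUE),
                                1)
  fid <- computeFid(traj, specN14, fieldX, fidLength = 128,
                    decimation = 16, stridePs = 5000)
  co <- secularCoefficients(traj, specN14, fieldX)[1, ]
  sticks <- eigen(nuclearF(co, 1), symmetric = TRUE)$values
  t <- fidTimes(fid) * 1e-12
  oracle <- sapply(t, function(tt) 0.5 * sum(exp(1i * sticks * tt)))
  expect_equal(fidValues(fid), as.complex(oracle), tolerance = 1e-9)
})

test_that("compiled and reference engines agree; invariants hold", {
  traj <- brownianRotation(4000, tauRotNs = 0.2, seed = 46)
  fid <- computeFid(traj, specN14, fieldX, fidLength = 32, decimation = 32,
                    stridePs = 1500)
  ref <- computeFid(traj, specN14, fieldX, fidLength = 32, decimation = 32,
                    stridePs = 1500, engine = "reference")
  expect_equal(fidValues(fid), fidValues(ref), tolerance = 1e-9)
  dg <- attr(fid, "diagnostics")
  expect_lt(dg$maxUnitarityDev, 1e-10)
  dgr <- attr(ref, "diagnostics")
  expect_lt(dgr$maxHermitianDev, 1e-9)   # sigma stays Hermitian
  expect_lt(dgr$maxTraceDev, 1e-9)       # trace conserved
})

test_that("window validation and Nyquist guard trigger", {
  traj <- brownianRotation(1000, tauRotNs = 0.2, seed = 47)
  expect_error(computeFid(traj, specN14, fieldX, fidLength = 1024,
                          decimation = 64), "exceeds the trajectory")
  expect_error(computeFid(traj, specN14, fieldX, fidLength = 8,
                          decimation = 8192, sweepMt = 12), "decimation")
})

test_that("broadening: disabled model is the identity; T2 sets the width", {
  t <- seq(0, 2e5, by = 50)
  fid <- new("Fid", timesPs = t,
             values = complex(real = exp(-t / 5e4)), carrier = "test")
  same <- applyBroadening(fid, broadeningModel(Inf, 0))
  expect_identical(fidValues(same), fidValues(fid))
  ## exponential FID -> Lorentzian of FWHM 1/(pi T2) on the frequency axis,
  ## i.e. the field-domain width of t2ToLorentzianWidth(T2)
  t2us <- 0.05
  fid2 <- new("Fid", timesPs = t,
              values = complex(real = exp(-t / (t2us * 1e6))),
              carrier = "test")
  sp <- absorptionSpectrum(fid2, specN14, sweepMt = 2, nPoints = 4096)
  half <- max(intensity(sp)) / 2
  above <- fieldAxis(sp)[intensity(sp) > half]
  fwhmUt <- (max(above) - min(above)) * 1e3
  expect_equal(fwhmUt, t2ToLorentzianWidth(t2us, gIso(specN14)),
               tolerance = 0.02)
})

test_that("gaussian convolution of a narrow line has the set width", {
  x <- seq(-1, 1, length.out = 4001)
  y <- numeric(4001); y[2001] <- 1
  sp <- esrSpectrum(x, y, mode = "absorption")
  out <- gaussianConvolve(sp, fwhmUt = 200)
  half <- max(intensity(out)) / 2
  above <- fieldAxis(out)[intensity(out) > half]
  expect_equal((max(above) - min(above)) * 1e3, 200, tolerance = 0.02)
})

test_that("modulated spectrum matches the analytic Lorentzian derivative", {
  ## small-modulation limit: s(w) ~ (Hm/4) * d/dw absorption
  t <- seq(0, 6e5, by = 100)
  t2us <- 0.05
  fid <- new("Fid", timesPs = t,
             values = complex(real = exp(-t / (t2us * 1e6))),
             carrier = "test")
  mod <- modulationConfig(0.002)   # well inside the linear regime
  sp <- modulatedSpectrum(fid, specN14, mod, sweepMt = 2, nPoints = 4096)
  x <- fieldAxis(sp)
  gamma <- t2ToLorentzianWidth(t2us, gIso(specN14)) / 1e3 / 2  # HWHM mT
  analytic <- -2 * gamma * x / pi / (x^2 + gamma^2)^2
  scale <- max(intensity(sp)) / max(analytic)
  rms <- sqrt(mean((intensity(sp) - scale * analytic)^2)) /
    max(abs(intensity(sp)))
  expect_lt(rms, 0.01)
  ## doubling Hm doubles the amplitude, shape unchanged
  sp2 <- modulatedSpectrum(fid, specN14, modulationConfig(0.004),
                           sweepMt = 2, nPoints = 4096)
  ratio <- max(intensity(sp2)) / max(intensity(sp))
  expect_equal(ratio, 2, tolerance = 0.01)
  shape <- cor(intensity(sp2), intensity(sp))
  expect_gt(shape, 0.9999)
  ## derivative of a symmetric line is antisymmetric about its centre
  expect_equal(intensity(sp), -rev(intensity(sp)), tolerance = 0.02)
  ## first-derivative spectra are baseline-closed
  expect_lt(abs(sum(intensity(sp))) / sum(abs(intensity(sp))), 0.01)
})

test_that("truncated FIDs trigger the ringing warning", {
  t <- seq(0, 1e4, by = 100)
  fid <- new("Fid", timesPs = t,
             values = complex(real = exp(-t / 1e6)), carrier = "test")
  expect_warning(modulatedSpectrum(fid, specN14, sweepMt = 2,
                                   nPoints = 512), "truncation")
})

test_that("fast-motion direct spectra resolve 2I+1 lines", {
  tr15 <- brownianRotation(3e5, tauRotNs = 0.2, seed = 48)
  fid <- computeFid(tr15, specN15, fieldX, fidLength = 2048,
                    decimation = 64, stridePs = 4000, sweepMt = 10)
  fid <- applyBroadening(fid, broadeningModel(0.3, 0))
  sp <- gaussianConvolve(absorptionSpectrum(fid, specN15, sweepMt = 10),
                         200)
  expect_identical(nrow(findPeaks(sp)), 2L)          # 15N doublet
  tr14 <- brownianRotation(3e5, tauRotNs = 0.2, seed = 48)
  fid14 <- computeFid(tr14, specN14, fieldX, fidLength = 2048,
                      decimation = 64, stridePs = 4000)
  fid14 <- applyBroadening(fid14, broadeningModel(0.3, 0))
  sp14 <- gaussianConvolve(absorptionSpectrum(fid14, specN14), 200)
  expect_identical(nrow(findPeaks(sp14)), 3L)        # 14N triplet
})

test_that("double integral of the first-derivative spectrum is conserved", {
  ## fixed broadening, two different motional models: equal spin counts
  mk <- function(tau, seed) {
    tr <- brownianRotation(4e5, tauRotNs = tau, seed = seed)
    simulateDirect(tr, specN14, fieldX, broadening = broadeningModel(0.5, 50),
                   fidLength = 2048, decimation = 64, stridePs = 4000)
  }
  s1 <- mk(0.2, 51); s2 <- mk(0.6, 52)
  dblInt <- function(sp) {
    x <- fieldAxis(sp)
    a <- pracma::cumtrapz(x, intensity(sp))[, 1]
    pracma::trapz(x, a)
  }
  expect_equal(dblInt(s1), dblInt(s2), tolerance = 0.01)
})
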