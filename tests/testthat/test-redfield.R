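test_that("isotropic-trajectory coupling correlations decay as exp(-6D tau)", {
  tau <- 0.2
  tr <- brownianRotation(4e5, tauRotNs = tau, seed = 61)
  sd <- correlationFunctions(tr, specN14, fieldX, maxLagPs = 2000)
  expect_true(sd@decays)
  csum <- sd@corr[1, 1, ] + sd@corr[2, 2, ] + sd@corr[3, 3, ] +
    sd@corr[4, 4, ]
  rel <- csum / csum[1]
  model <- exp(-sd@lagPs / (tau * 1000))
  expect_lt(max(abs(rel - model)), 0.05)
  expect_equal(sd@tauCPs, tau * 1000, tolerance = 0.1)
})

test_that("static trajectories are flagged and rejected by Redfield", {
  frozen <- orientationTrajectory(
    matrix(rep(randomQuats(1, seed = 62), each = 5000), 5000, 4,
           byrow = FALSE), 1, normalize = TRUE)
  expect_warning(sd <- correlationFunctions(frozen, specN14, fieldX,
                                            maxLagPs = 500), "not decay")
  expect_false(sd@decays)
  expect_error(suppressWarnings(buildRedfield(sd, specN14)), "invalid")
})

test_that("spectral densities obey the Cauchy-Schwarz bound", {
  tr <- brownianRotation(3e5, tauRotNs = 0.3, seed = 63)
  sd <- correlationFunctions(tr, specN14, fieldX, maxLagPs = 2500)
  for (om in c(0, 1e8, 2.8e8)) {
    J <- spectralDensityMatrix(sd, om)
    for (p in 1:4) {
      expect_gte(Re(J[p, p]), 0)
      for (q in 1:4)
        expect_lte(Mod(J[p, q])^2,
                   1.05 * Re(J[p, p]) * Re(J[q, q]) + 1e-10)
    }
  }
})

test_that("zero spectral densities give a purely coherent model", {
  tr <- brownianRotation(5e4, tauRotNs = 0.2, seed = 64)
  sd <- correlationFunctions(tr, specN14, fieldX, maxLagPs = 800)
  sd@corr[, , ] <- 0
  sd@tailAmp <- matrix(0, 4, 4)
  m <- buildRedfield(sd, specN14)
  lam <- eigen(m@liouvillian, only.values = TRUE)$values
  expect_lt(max(abs(Re(lam))), 1)   # no relaxation (rad/s scale ~1e8)
})

test_that("relaxation eigenvalues are decaying for physical input", {
  tr <- brownianRotation(3e5, tauRotNs = 0.5, seed = 65)
  sd <- correlationFunctions(tr, specN14, fieldX, maxLagPs = 4000)
  m <- buildRedfield(sd, specN14)
  lam <- eigen(m@liouvillian, only.values = TRUE)$values
  expect_lt(max(Re(lam)), 1e-6 * max(-Re(lam)))
})

test_that("cross-correlations control the 15N doublet asymmetry", {
  tr <- brownianRotation(1e6, tauRotNs = 1, seed = 66)
  sd <- correlationFunctions(tr, specN15, fieldX, maxLagPs = 8000)
  asym <- function(includeCross) {
    m <- buildRedfield(sd, specN15, includeCrossCorrelations = includeCross)
    sp <- redfieldSpectrum(m, broadeningModel(Inf, 20),
                           mode = "absorption", sweepMt = 10,
                           fidLength = 4096, dtPs = 128)
    pk <- findPeaks(sp, frac = 0.1)
    expect_identical(nrow(pk), 2L)
    abs(diff(pk$height)) / max(pk$height)
  }
  expect_lt(asym(FALSE), 0.01)       # symmetric doublet without cross terms
  expect_gt(asym(TRUE), 0.05)        # TROSY-like asymmetry with them
})

test_that("cross terms off: the two 15N electron transitions relax equally", {
  tr <- brownianRotation(6e5, tauRotNs = 0.5, seed = 67)
  sd <- correlationFunctions(tr, specN15, fieldX, maxLagPs = 5000)
  m <- buildRedfield(sd, specN15, includeCrossCorrelations = FALSE)
  lw <- redfieldLinewidths(m)
  main <- lw[abs(complex(real = lw$weightRe, imaginary = lw$weightIm)) >
               0.25, ]
  expect_identical(nrow(main), 2L)
  expect_equal(main$rate[1], main$rate[2], tolerance = 0.02)
  ## 15N lines sit at +/- Aiso/2 offsets
  aRad <- aIso(specN15) * 2e6 * pi
  expect_equal(sort(main$frequency), sort(c(-aRad / 2, aRad / 2)),
               tolerance = 0.02)
})

test_that("14N fast-motion spectrum has the narrowest central line", {
  tr <- brownianRotation(8e5, tauRotNs = 0.5, seed = 68)
  sd <- correlationFunctions(tr, specN14, fieldX, maxLagPs = 5000)
  m <- buildRedfield(sd, specN14)
  sp <- redfieldSpectrum(m, broadeningModel(0.83, 126))
  d <- spectrumDescriptors(sp, specN14)
  expect_gt(d$ratioH0Hm1, 1)
  expect_lt(d$deltaUt[2], d$deltaUt[3])   # centre narrower than high-field
})

test_that("Redfield rates match the closed-form linewidth formula", {
  tr <- brownianRotation(8e5, tauRotNs = 0.3, seed = 69)
  sd <- correlationFunctions(tr, specN14, fieldX, maxLagPs = 3000)
  m <- buildRedfield(sd, specN14, dynamicShifts = FALSE)
  lw <- redfieldLinewidths(m)
  main <- lw[abs(complex(real = lw$weightRe, imaginary = lw$weightIm)) >
               0.25, ]
  main <- main[order(-main$frequency), ]     # mI = +1, 0, -1
  oracle <- closedFormLinewidths(sd, specN14)
  expect_equal(main$rate, oracle$rate, tolerance = 0.03)
})

test_that("validity report reproduces the known regimes", {
  fast <- brownianRotation(8e5, tauRotNs = 1, seed = 70)
  repFast <- validityReport(fast, specN14, fieldX, maxLagPs = 8000)
  expect_identical(repFast$verdict, "valid")
  expect_equal(repFast$tauCNs, 1, tolerance = 0.15)
  expect_gt(repFast$t2eNs, 30)   # long electron coherence time

  slow <- brownianRotation(1e6, tauRotNs = 3.2, seed = 71)
  repSlow <- suppressWarnings(validityReport(slow, specN14, fieldX,
                                             maxLagPs = 2e4))
  expect_true(repSlow$verdict %in% c("marginal", "invalid"))
  expect_gt(repSlow$ratio, repFast$ratio)
})
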