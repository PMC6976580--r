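test_that("Voigt profile matches a brute-force numerical convolution", {
  lor <- 0.12; gau <- 0.3   # mT
  x <- seq(-3, 3, by = 0.002)
  v <- voigtProfile(x, lor, gau)
  ## oracle: discrete convolution of the pure profiles
  g <- voigtProfile(x, 0, gau)
  l <- voigtProfile(x, lor, 0)
  conv <- stats::convolve(l, rev(g), type = "open") * 0.002
  mid <- (length(conv) + 1) / 2
  oracle <- conv[(mid - (length(x) - 1) / 2):(mid + (length(x) - 1) / 2)]
  expect_lt(max(abs(v - oracle)) / max(v), 5e-3)
  ## unit area (wide range to capture the Lorentzian tails)
  xw <- seq(-80, 80, by = 0.01)
  expect_equal(pracma::trapz(xw, voigtProfile(xw, lor, gau)), 1,
               tolerance = 1e-3)
  ## pure limits
  gam <- lor / 2
  expect_equal(voigtProfile(x, lor, 0), gam / pi / (x^2 + gam^2),
               tolerance = 1e-12)
  sig <- gau / (2 * sqrt(2 * log(2)))
  expect_equal(voigtProfile(x, 0, gau),
               exp(-x^2 / (2 * sig^2)) / (sig * sqrt(2 * pi)),
               tolerance = 1e-9)
})

test_that("analytic Voigt derivative matches numerical differentiation", {
  x <- seq(-1, 1, by = 0.01)
  h <- 1e-6
  num <- (voigtProfile(x + h, 0.08, 0.15) -
            voigtProfile(x - h, 0.08, 0.15)) / (2 * h)
  dv <- voigtDerivative(x, 0.08, 0.15)
  expect_lt(max(abs(dv - num)) / max(abs(dv)), 1e-4)
})

test_that("far-wing Voigt evaluation stays finite and Lorentzian-like", {
  x <- seq(50, 500, by = 50)   # hundreds of Gaussian sigmas out
  v <- voigtProfile(x, 0.1, 0.1)
  expect_true(all(is.finite(v)))
  expect_equal(v, 0.05 / pi / x^2, tolerance = 0.01)
})

test_that("linear baseline correction recovers exact ramps", {
  x <- seq(-6, 6, length.out = 2048)
  ## Gaussian-derivative line: negligible leakage into the wing intervals
  line <- voigtDerivative(x, 0, 0.4)
  sp <- esrSpectrum(x, line + 0.37 + 0.21 * x, mode = "first_derivative")
  out <- baselineCorrect(sp)
  expect_lt(max(abs(intensity(out) - line)), 1e-10)
  flat <- baselineCorrect(esrSpectrum(x, line, mode = "first_derivative"))
  expect_lt(max(abs(intensity(flat) - line)), 1e-10)
  expect_error(baselineCorrect(esrSpectrum(x / 100, line,
                                           mode = "first_derivative")),
               "intervals")
})

test_that("phase correction rotates between absorption and dispersion", {
  x <- seq(-8, 8, length.out = 4096)
  gam <- 0.2
  absn <- gam / pi / (x^2 + gam^2)
  disp <- x / pi / (x^2 + gam^2)
  phi <- 35
  mixed <- cos(phi * pi / 180) * absn + sin(phi * pi / 180) * disp
  sp <- esrSpectrum(x, mixed, mode = "absorption")
  expect_identical(intensity(phaseCorrect(sp, 0)), mixed)
  ## rotating back by -phi recovers pure absorption (away from edges)
  rec <- intensity(phaseCorrect(sp, -phi))
  core <- abs(x) < 4
  expect_lt(max(abs(rec[core] - absn[core])) / max(absn), 0.02)
  ## +90 twice then sign flip returns the original
  twice <- phaseCorrect(phaseCorrect(sp, 90), 90)
  expect_lt(max(abs(intensity(twice)[core] + mixed[core])) / max(absn),
            0.05)
})

test_that("integration of a derivative recovers the absorption shape", {
  x <- seq(-6, 6, length.out = 4096)
  sig <- 0.3
  gauss <- exp(-x^2 / (2 * sig^2))
  dgauss <- -x / sig^2 * gauss
  sp <- esrSpectrum(x, dgauss, mode = "first_derivative")
  out <- integrateToAbsorption(sp)
  scale <- pracma::trapz(x, intensity(out)) / pracma::trapz(x, gauss)
  expect_lt(sqrt(mean((intensity(out) - scale * gauss)^2)) / max(gauss),
            0.005)
  zero <- integrateToAbsorption(esrSpectrum(x, numeric(4096),
                                            mode = "first_derivative"))
  expect_identical(intensity(zero), numeric(4096))
  ## antisymmetric derivative -> symmetric positive peak
  expect_equal(intensity(out), rev(intensity(out)), tolerance = 1e-8)
  expect_gt(min(intensity(out)[abs(x) < sig]), 0)
})

test_that("single-line Voigt fits recover known parameters", {
  sp <- synthSpectrum(0.2, 0.05, 0.1, 3.7)
  fit <- fitVoigtLine(sp, c(-1, 1.4))
  expect_equal(fit$center, 0.2, tolerance = 1e-3)
  expect_equal(fit$lorFwhmUt, 50, tolerance = 0.01 * 50)
  expect_equal(fit$gaussFwhmUt, 100, tolerance = 0.01 * 100)

  ## pure Lorentzian line: fitted Gaussian collapses, Delta_pp = w/sqrt(3)
  spL <- synthSpectrum(0, 0.09, 0, 2)
  fitL <- fitVoigtLine(spL, c(-1, 1))
  expect_lt(fitL$gaussFwhmUt, 5)
  ext <- spinESR:::.voigtLineExtrema(fitL$center, fitL$lorFwhmUt / 1e3,
                                     fitL$gaussFwhmUt / 1e3,
                                     fitL$amplitude, 0.8)
  expect_equal((ext$xMin - ext$xMax) * 1e3, 90 / sqrt(3), tolerance = 0.02)
  expect_error(fitVoigtLine(synthSpectrum(0, 0.05, 0, 1), c(2, 4)),
               "extremum")
})

test_that("fit is invariant under amplitude scaling and axis shift", {
  base <- synthSpectrum(0, 0.06, 0.12, 1)
  f0 <- fitVoigtLine(base, c(-1, 1))
  shifted <- esrSpectrum(fieldAxis(base) + 0.8, 25 * intensity(base),
                         mode = "first_derivative")
  f1 <- fitVoigtLine(shifted, c(-0.2, 1.8))
  expect_equal(f1$lorFwhmUt, f0$lorFwhmUt, tolerance = 1e-3)
  expect_equal(f1$gaussFwhmUt, f0$gaussFwhmUt, tolerance = 1e-3)
  expect_equal(f1$center - f0$center, 0.8, tolerance = 1e-6)
})

test_that("descriptors: symmetric triplet gives unit ratio; noise robust", {
  aMt <- convertHyperfine(aIso(specN14), "MHz", "mT", gIso(specN14))
  centers <- c(-aMt, 0, aMt)
  sp <- synthSpectrum(centers, rep(0.05, 3), rep(0.12, 3), rep(1, 3))
  d <- spectrumDescriptors(sp, specN14)
  expect_equal(d$ratioH0Hm1, 1, tolerance = 1e-3)
  expect_equal(d$deltaUt[1], d$deltaUt[3], tolerance = 1e-3)
  ## with noise at SNR 50 the widths are still recovered within a few %
  set.seed(81)
  noisy <- esrSpectrum(fieldAxis(sp),
                       intensity(sp) + rnorm(length(fieldAxis(sp)),
                                             sd = max(intensity(sp)) / 50),
                       mode = "first_derivative")
  dn <- spectrumDescriptors(noisy, specN14)
  expect_equal(dn$deltaUt, d$deltaUt, tolerance = 0.05)
})

test_that("doubling the width of a derivative Lorentzian divides the
           amplitude by four at equal area", {
  x <- seq(-2, 2, length.out = 8192)
  a1 <- voigtDerivative(x, 0.05, 0)
  a2 <- voigtDerivative(x, 0.10, 0)
  h <- function(y) max(y) - min(y)
  expect_equal(h(a1) / h(a2), 4, tolerance = 0.01)
})

test_that("collective air/degassed fit separates G and L_O2", {
  aMt <- convertHyperfine(aIso(specN14), "MHz", "mT", gIso(specN14))
  centers <- c(-aMt, 0, aMt)
  Lint <- c(0.030, 0.026, 0.034)      # intrinsic Lorentzians, mT
  G <- 0.126; LO2 <- 0.0135
  degassed <- synthSpectrum(centers, Lint, rep(G, 3), c(1, 1.05, 0.95))
  air <- synthSpectrum(centers, Lint + LO2, rep(G, 3), c(1, 1.05, 0.95))
  fit <- collectiveVoigtFit(air, degassed, specN14)
  expect_equal(fit$gaussFwhmUt, 126, tolerance = 0.02 * 126)
  expect_equal(fit$lO2FwhmUt, 13.5, tolerance = 0.02 * 13.5)
  expect_false(fit$flagged)
  ## identical pair: L_O2 collapses to zero and is flagged unidentifiable
  same <- collectiveVoigtFit(degassed, degassed, specN14)
  expect_lt(same$lO2FwhmUt, 1)
})

test_that("width <-> T2 conversion round trips and has the right limits", {
  t2 <- lorentzianWidthToT2(13.5, 2.0059)
  expect_equal(t2ToLorentzianWidth(t2, 2.0059), 13.5, tolerance = 1e-12)
  expect_lt(lorentzianWidthToT2(1e9), 1e-6)   # infinite width -> T2 -> 0
  expect_error(lorentzianWidthToT2(-1), "positive")
  expect_error(t2ToLorentzianWidth(0), "positive")
})
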