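## Spectral post-processing and Voigt-profile fitting: baseline and phase
## correction, integration to absorption mode, per-line first-derivative
## Voigt fits with the 80-percent window rule, peak-to-peak descriptors,
## collective air/degassed fitting and width <-> T2 conversions.

## Faddeeva function w(z) = exp(-z^2) erfc(-iz) for Im(z) >= 0, by
## Weideman's single rational approximation (uniformly accurate over the
## closed upper half plane; no region switching, hence smooth to machine
## precision -- essential for derivative-based fitting).
.faddeevaCache <- new.env(parent = emptyenv())

.faddeevaCoef <- function(N = 40) {
  key <- as.character(N)
  if (!is.null(.faddeevaCache[[key]])) return(.faddeevaCache[[key]])
  M <- 2L * N
  M2 <- 2L * M
  k <- seq(-M + 1L, M - 1L)
  Lw <- sqrt(N / sqrt(2))
  theta <- k * pi / M
  t <- Lw * tan(theta / 2)
  f <- exp(-t^2) * (Lw^2 + t^2)
  f <- c(0, f)
  ## reorder so index 0 comes first (fftshift), then Fourier coefficients
  half <- c(f[(M + 1L):M2], f[1L:M])
  a <- Re(stats::fft(half)) / M2
  a <- rev(a[2L:(N + 1L)])
  out <- list(L = Lw, a = a)
  .faddeevaCache[[key]] <- out
  out
}

.faddeeva <- function(z) {
  cf <- .faddeevaCoef()
  Lw <- cf$L; a <- cf$a
  Z <- (Lw + 1i * z) / (Lw - 1i * z)
  p <- 0
  for (ak in a) p <- p * Z + ak        # polyval, highest order first
  2 * p / (Lw - 1i * z)^2 + (1 / sqrt(pi)) / (Lw - 1i * z)
}

#' Voigt profile and its analytic first derivative
#'
#' Area-normalised Voigt profile: the convolution of a Lorentzian of full
#' width `lorFwhm` and a Gaussian of full width `gaussFwhm`, evaluated via
#' the scaled complex error function. `voigtDerivative` is the analytic
#' derivative with respect to `x` (stable for fitting narrow
#' first-derivative ESR lines; no finite differences involved). Either
#' width may be zero, recovering the pure Gaussian or pure Lorentzian
#' limit.
#'
#' @param x Abscissa (same units as the widths; typically mT).
#' @param lorFwhm Lorentzian FWHH (>= 0).
#' @param gaussFwhm Gaussian FWHH (>= 0).
#' @return Numeric vector; the profile has unit area.
#' @export
voigtProfile <- function(x, lorFwhm, gaussFwhm) {
  gam <- lorFwhm / 2
  sig <- gaussFwhm / (2 * sqrt(2 * log(2)))
  if (gaussFwhm <= 0) {
    if (lorFwhm <= 0) stop("at least one width must be positive")
    return(gam / pi / (x^2 + gam^2))
  }
  if (lorFwhm <= 0)
    return(exp(-x^2 / (2 * sig^2)) / (sig * sqrt(2 * pi)))
  z <- (x + 1i * gam) / (sig * sqrt(2))
  Re(.faddeeva(z)) / (sig * sqrt(2 * pi))
}

#' @rdname voigtProfile
#' @export
voigtDerivative <- function(x, lorFwhm, gaussFwhm) {
  gam <- lorFwhm / 2
  sig <- gaussFwhm / (2 * sqrt(2 * log(2)))
  if (gaussFwhm <= 0) {
    if (lorFwhm <= 0) stop("at least one width must be positive")
    return(-2 * gam * x / pi / (x^2 + gam^2)^2)
  }
  if (lorFwhm <= 0)
    return(-x / sig^2 * exp(-x^2 / (2 * sig^2)) / (sig * sqrt(2 * pi)))
  z <- (x + 1i * gam) / (sig * sqrt(2))
  wz <- .faddeeva(z)
  dw <- -2 * z * wz + 2i / sqrt(pi)
  Re(dw) / (sig^2 * 2 * sqrt(pi))
}

#' Linear baseline correction of a first-derivative spectrum
#'
#' Fits a straight line over the flat wing intervals and subtracts it.
#' Default intervals are `[-6, -3.5]` and `[3.5, 6]` mT for 14N spectra and
#' `[-5, -3.5]` and `[3.5, 5]` mT for 15N spectra.
#'
#' @param spectrum An [EsrSpectrum-class].
#' @param intervals List of `c(lo, hi)` field intervals (mT); when `NULL`,
#'   chosen by `isotope`.
#' @param isotope `"14N"` or `"15N"` (selects default intervals).
#' @return The corrected [EsrSpectrum-class].
#' @export
baselineCorrect <- function(spectrum, intervals = NULL, isotope = "14N") {
  stopifnot(is(spectrum, "EsrSpectrum"))
  if (is.null(intervals)) {
    intervals <- if (isotope == "15N")
      list(c(-5, -3.5), c(3.5, 5)) else list(c(-6, -3.5), c(3.5, 6))
  }
  x <- spectrum@fieldMt
  sel <- Reduce(`|`, lapply(intervals, function(iv) x >= iv[1] & x <= iv[2]))
  if (!any(sel)) stop("baseline intervals do not overlap the field axis")
  fit <- stats::lm.fit(cbind(1, x[sel]), spectrum@intensity[sel])
  spectrum@intensity <- spectrum@intensity -
    (fit$coefficients[1] + fit$coefficients[2] * x)
  spectrum
}

## FFT analytic signal; returns the quadrature (Hilbert transform) of y
.hilbertQuadrature <- function(y) {
  n <- length(y)
  f <- stats::fft(y)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Im(stats::fft(f * h, inverse = TRUE) / n)
}

#' Zero-order phase correction via the Hilbert transform
#'
#' Constructs the quadrature (dispersion) component of the spectrum with
#' the analytic-signal Hilbert transform and returns
#' `cos(phi) * spectrum + sin(phi) * quadrature`, the standard algorithm
#' for correcting small phase imperfections of absorption-mode spectra.
#'
#' @param spectrum An [EsrSpectrum-class] on a uniform axis.
#' @param angleDeg Phase angle in degrees (0 returns the input).
#' @return The phased [EsrSpectrum-class].
#' @export
phaseCorrect <- function(spectrum, angleDeg) {
  stopifnot(is(spectrum, "EsrSpectrum"))
  phi <- angleDeg * pi / 180
  if (phi == 0) return(spectrum)
  quad <- .hilbertQuadrature(spectrum@intensity)
  spectrum@intensity <- cos(phi) * spectrum@intensity + sin(phi) * quad
  spectrum
}

#' Integrate a first-derivative spectrum to absorption mode
#'
#' Cumulative trapezoidal integration followed by re-zeroing on the mean of
#' the wing intervals.
#'
#' @param spectrum A first-derivative [EsrSpectrum-class].
#' @param wingFraction Fraction of the axis at each end treated as signal-
#'   free wings (default 0.1).
#' @return An absorption-mode [EsrSpectrum-class].
#' @export
integrateToAbsorption <- function(spectrum, wingFraction = 0.1) {
  stopifnot(is(spectrum, "EsrSpectrum"))
  x <- spectrum@fieldMt
  y <- pracma::cumtrapz(x, spectrum@intensity)[, 1]
  n <- length(x)
  k <- max(1L, floor(wingFraction * n))
  y <- y - mean(y[c(seq_len(k), seq(n - k + 1L, n))])
  esrSpectrum(x, y, mode = "absorption", meta = spectrum@meta)
}

## locate the max/min pair of one first-derivative line within a region
.extremumPair <- function(x, y) {
  iMax <- which.max(y); iMin <- which.min(y)
  if (!(iMax < iMin) || y[iMax] <= 0 || y[iMin] >= 0)
    return(NULL)
  list(iMax = iMax, iMin = iMin)
}

#' Fit a single first-derivative Voigt line
#'
#' Locates the maximum/minimum pair of the line inside `region`, restricts
#' the fit window to the interval between the leftmost point at 80 percent
#' of the maximal intensity and the rightmost point at 80 percent of the
#' minimal intensity, and least-squares fits the analytic first derivative
#' of the Voigt function over that window.
#'
#' @param spectrum A first-derivative [EsrSpectrum-class].
#' @param region `c(lo, hi)` field interval (mT) containing one line.
#' @return List with `center` (mT), `lorFwhmUt`, `gaussFwhmUt` (uT),
#'   `amplitude` (area-like scale), `residual` (RMS), `windowMt` and the
#'   `nls` fit object.
#' @export
fitVoigtLine <- function(spectrum, region) {
  stopifnot(is(spectrum, "EsrSpectrum"))
  sel <- spectrum@fieldMt >= region[1] & spectrum@fieldMt <= region[2]
  if (sum(sel) < 8) stop("fit region contains too few points")
  x <- spectrum@fieldMt[sel]; y <- spectrum@intensity[sel]
  ext <- .extremumPair(x, y)
  if (is.null(ext))
    stop("no maximum/minimum extremum pair found in region [",
         region[1], ", ", region[2], "] mT")
  yMax <- y[ext$iMax]; yMin <- y[ext$iMin]
  iLeft <- which(y >= 0.8 * yMax)[1]
  iRight <- max(which(y <= 0.8 * yMin))
  win <- x >= x[iLeft] & x <= x[iRight]
  xw <- x[win]; yw <- y[win]
  dpp <- x[ext$iMin] - x[ext$iMax]
  c0 <- (x[ext$iMin] + x[ext$iMax]) / 2
  ## symmetric width starts can make the lor/gauss gradient columns
  ## collinear over the narrow 80% window; try asymmetric splits
  splits <- list(c(1, 1), c(1.7, 0.2), c(0.2, 1.1), c(0.8, 0.8))
  fit <- NULL
  for (spl in splits) {
    start <- list(center = c0, lor = spl[1] * dpp, gauss = spl[2] * dpp,
                  amp = yMax /
                    max(voigtDerivative(-dpp / 2, spl[1] * dpp,
                                        spl[2] * dpp), 1e-12))
    cand <- tryCatch(
      minpack.lm::nlsLM(
        yw ~ amp * voigtDerivative(xw - center, lor, gauss),
        start = start,
        lower = c(region[1], 0, 0, -Inf),
        upper = c(region[2], Inf, Inf, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || deviance(cand) < deviance(fit)))
      fit <- cand
  }
  if (is.null(fit))
    stop("Voigt line fit failed to converge in region [", region[1], ", ",
         region[2], "] mT")
  cf <- coef(fit)
  list(center = cf[["center"]], lorFwhmUt = cf[["lor"]] * 1e3,
       gaussFwhmUt = cf[["gauss"]] * 1e3, amplitude = cf[["amp"]],
       residual = sqrt(mean(residuals(fit)^2)),
       windowMt = c(x[iLeft], x[iRight]), fit = fit)
}

## extrema of the best-fit first-derivative Voigt line
.voigtLineExtrema <- function(center, lorFwhm, gaussFwhm, amp, halfSpan) {
  f <- function(x) amp * voigtDerivative(x - center, lorFwhm, gaussFwhm)
  up <- stats::optimize(f, c(center - halfSpan, center), maximum = TRUE)
  dn <- stats::optimize(f, c(center, center + halfSpan))
  if (amp < 0) {  # inverted line
    up <- stats::optimize(f, c(center, center + halfSpan), maximum = TRUE)
    dn <- stats::optimize(f, c(center - halfSpan, center))
  }
  list(xMax = up$maximum, yMax = up$objective,
       xMin = dn$minimum, yMin = dn$objective)
}

#' Peak-to-peak descriptors of a multiline first-derivative spectrum
#'
#' Fits each hyperfine line with a first-derivative Voigt profile (windows
#' seeded at the first-order resonance offsets `-mI Aiso` mapped to field
#' units) and reports, per line, the peak-to-peak width `Delta_(i)` and
#' amplitude `h_(i)` measured on the best-fit function, plus the central to
#' high-field amplitude ratio `h(0)/h(-1)`. Lines are ordered low field to
#' high field, i.e. mI = (+1, 0, -1) for 14N and (+1/2, -1/2) for 15N.
#'
#' @param spectrum A first-derivative [EsrSpectrum-class].
#' @param spec The [SpinSystem-class] (supplies line-position seeds).
#' @return List with `deltaUt` (pp widths, uT), `hPp` (pp amplitudes),
#'   `ratioH0Hm1`, `centersMt` and the per-line fits.
#' @export
spectrumDescriptors <- function(spectrum, spec) {
  stopifnot(is(spectrum, "EsrSpectrum"), is(spec, "SpinSystem"))
  aMt <- convertHyperfine(aIso(spec), "MHz", "mT", gIso(spec))
  mI <- if (spec@nuclearSpin == 1) c(1, 0, -1) else c(0.5, -0.5)
  ## field mapping dB = -hbar w / (g muB): mI = +1 resonates at low field
  centers <- sort(-mI * aMt)
  spacing <- if (length(centers) > 1) min(diff(centers)) else aMt
  fits <- vector("list", length(centers))
  for (k in seq_along(centers)) {
    region <- centers[k] + c(-0.48, 0.48) * spacing
    fits[[k]] <- tryCatch(fitVoigtLine(spectrum, region),
                          error = function(e)
                            stop("line ", k, " (mI = ", sort(mI, TRUE)[k],
                                 ", near ", signif(centers[k], 3),
                                 " mT) could not be resolved: ",
                                 conditionMessage(e), call. = FALSE))
  }
  delta <- numeric(length(fits)); h <- numeric(length(fits))
  for (k in seq_along(fits)) {
    f <- fits[[k]]
    ex <- .voigtLineExtrema(f$center, f$lorFwhmUt / 1e3, f$gaussFwhmUt / 1e3,
                            f$amplitude, spacing / 2)
    delta[k] <- (ex$xMin - ex$xMax) * 1e3
    h[k] <- ex$yMax - ex$yMin
  }
  nl <- length(fits)
  ratio <- if (nl == 3) h[2] / h[3] else h[1] / h[2]
  list(deltaUt = abs(delta), hPp = h, ratioH0Hm1 = ratio,
       centersMt = vapply(fits, `[[`, numeric(1), "center"), fits = fits)
}

#' Collective Voigt fit of an air-equilibrated / degassed spectrum pair
#'
#' Joint least squares over both spectra with a shared Gaussian width `G`,
#' shared line centers and per-line Lorentzian widths `L_(i)`; the lines of
#' the air-equilibrated spectrum carry the additional oxygen Lorentzian
#' `L_O2` (widths `L_(i) + L_O2`), the degassed lines carry `L_(i)` alone.
#' This is the analysis that separates the oxygen contribution from the
#' inhomogeneous broadening in spectra of the free label.
#'
#' @param spectrumAir,spectrumDegassed First-derivative
#'   [EsrSpectrum-class] objects sharing line positions.
#' @param spec The [SpinSystem-class] (line seeds).
#' @return List with `gaussFwhmUt`, `lO2FwhmUt`, `lorFwhmUt` (per line),
#'   `centersMt`, `residual`, `flagged` (TRUE when L_O2 is unidentifiable)
#'   and the joint `nls` fit.
#' @export
collectiveVoigtFit <- function(spectrumAir, spectrumDegassed, spec) {
  stopifnot(is(spectrumAir, "EsrSpectrum"), is(spectrumDegassed, "EsrSpectrum"))
  aMt <- convertHyperfine(aIso(spec), "MHz", "mT", gIso(spec))
  mI <- if (spec@nuclearSpin == 1) c(1, 0, -1) else c(0.5, -0.5)
  centers0 <- sort(-mI * aMt)
  nl <- length(centers0)
  ## per-line data windows on both spectra
  spacing <- if (nl > 1) min(diff(centers0)) else aMt
  mkData <- function(sp, which) {
    sel <- Reduce(`|`, lapply(centers0, function(c0)
      sp@fieldMt >= c0 - 0.48 * spacing & sp@fieldMt <= c0 + 0.48 * spacing))
    data.frame(x = sp@fieldMt[sel], y = sp@intensity[sel], air = which)
  }
  dat <- rbind(mkData(spectrumAir, 1), mkData(spectrumDegassed, 0))
  seed <- lapply(seq_len(nl), function(k)
    fitVoigtLine(spectrumDegassed, centers0[k] + c(-0.48, 0.48) * spacing))
  seedAir <- lapply(seq_len(nl), function(k)
    fitVoigtLine(spectrumAir, centers0[k] + c(-0.48, 0.48) * spacing))
  lo2Init <- max(1e-4, mean(vapply(seedAir, `[[`, numeric(1), "lorFwhmUt") -
                              vapply(seed, `[[`, numeric(1), "lorFwhmUt")) /
                    1e3)
  par0 <- c(G = mean(vapply(seed, `[[`, numeric(1), "gaussFwhmUt")) / 1e3,
            LO2 = lo2Init,
            setNames(vapply(seed, `[[`, numeric(1), "center"),
                     paste0("c", seq_len(nl))),
            setNames(pmax(vapply(seed, `[[`, numeric(1), "lorFwhmUt") / 1e3,
                          1e-4), paste0("L", seq_len(nl))),
            setNames(vapply(seed, `[[`, numeric(1), "amplitude"),
                     paste0("aD", seq_len(nl))),
            setNames(vapply(seedAir, `[[`, numeric(1), "amplitude"),
                     paste0("aA", seq_len(nl))))
  modelFun <- function(p, dat) {
    out <- numeric(nrow(dat))
    for (k in seq_len(nl)) {
      ck <- p[[paste0("c", k)]]
      Lk <- p[[paste0("L", k)]]
      degassed <- dat$air == 0
      out[degassed] <- out[degassed] + p[[paste0("aD", k)]] *
        voigtDerivative(dat$x[degassed] - ck, Lk, p[["G"]])
      out[!degassed] <- out[!degassed] + p[[paste0("aA", k)]] *
        voigtDerivative(dat$x[!degassed] - ck, Lk + p[["LO2"]], p[["G"]])
    }
    out
  }
  resFun <- function(p) {
    p <- as.list(p)
    dat$y - modelFun(p, dat)
  }
  lower <- rep(-Inf, length(par0)); names(lower) <- names(par0)
  lower[c("G", "LO2", paste0("L", seq_len(nl)))] <- 0
  fit <- minpack.lm::nls.lm(par = par0, fn = resFun, lower = lower,
                            control = minpack.lm::nls.lm.control(maxiter = 400))
  p <- as.list(coef(fit))
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA, length(par0)))
  names(se) <- names(par0)
  lo2 <- p[["LO2"]]
  flagged <- is.na(se[["LO2"]]) || (lo2 < 2 * se[["LO2"]] && lo2 < 1e-3) ||
    se[["LO2"]] > abs(lo2)
  list(gaussFwhmUt = p[["G"]] * 1e3, lO2FwhmUt = lo2 * 1e3,
       lorFwhmUt = vapply(seq_len(nl), function(k)
         p[[paste0("L", k)]] * 1e3, numeric(1)),
       centersMt = vapply(seq_len(nl), function(k)
         p[[paste0("c", k)]], numeric(1)),
       residual = sqrt(mean(residuals(fit)^2)), flagged = flagged,
       fit = fit)
}

#' Convert a Lorentzian field width to the electron T2 (and back)
#'
#' `T2 = h / (gIso muB pi dB_FWHH)`: a homogeneous Lorentzian of full width
#' at half height `dB` on the field axis corresponds to transverse
#' relaxation with time constant T2. The round trip is an identity.
#'
#' @param fwhmUt Lorentzian FWHH in microtesla.
#' @param gIso Isotropic g value.
#' @return `lorentzianWidthToT2`: T2 in microseconds.
#' @export
lorentzianWidthToT2 <- function(fwhmUt, gIso = 2.0059) {
  if (any(fwhmUt <= 0)) stop("width must be positive")
  dBT <- fwhmUt * 1e-6
  t2s <- physicalConstants$h / (gIso * physicalConstants$muB * pi * dBT)
  t2s * 1e6
}

#' @rdname lorentzianWidthToT2
#' @param t2Us T2 in microseconds.
#' @return `t2ToLorentzianWidth`: FWHH in microtesla.
#' @export
t2ToLorentzianWidth <- function(t2Us, gIso = 2.0059) {
  if (any(t2Us <= 0)) stop("T2 must be positive")
  physicalConstants$h / (gIso * physicalConstants$muB * pi * t2Us * 1e-6) * 1e6
}
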