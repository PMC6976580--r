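## Shared fixtures and oracles for the test suite. Everything is built in
## code at test time; no stored data.

specN14 <- spinSystem("14N")
specN15 <- scaleTo15N(specN14)
fieldX <- fieldConfig(gIso = gIso(specN14))

## random unit quaternions, reproducible
randomQuats <- function(n, seed = 42) {
  set.seed(seed)
  q <- matrix(rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

## small-matrix helpers
hermDev <- function(M) max(Mod(M - Conj(t(M))))
commutator <- function(A, B) A %*% B - B %*% A

## independent matrix exponential via eigendecomposition (oracle)
expmHermitian <- function(H, scale = 1) {
  e <- eigen(H, symmetric = TRUE)
  e$vectors %*% (exp(1i * e$values * scale) * Conj(t(e$vectors)))
}

## nuclear block Hamiltonian F = cg 1 + ax Ix + ay Iy + az Iz (rad/s);
## its eigenvalues are the stick positions of a frozen orientation
nuclearF <- function(coefRow, nuclearSpin) {
  I <- spinESR:::.angularMomentum(nuclearSpin)
  coefRow[1] * diag(nrow(I$Jz)) + coefRow[2] * I$Jx +
    coefRow[3] * I$Jy + coefRow[4] * I$Jz
}

## closed-form motional-narrowing linewidths A + B mI + C mI^2 plus
## nuclear-flip lifetime terms, computed from the same spectral densities
## that feed the Redfield supermatrix but through the textbook per-line
## formula (independent of the supermatrix assembly and diagonalisation).
closedFormLinewidths <- function(sd, spec) {
  I <- spinESR:::.angularMomentum(spec@nuclearSpin)
  dI <- nrow(I$Jz)
  mVals <- diag(Re(I$Jz))
  Hbar <- nuclearF(sd@meanCoef, spec@nuclearSpin) / 2
  eps <- sort(eigen(Hbar, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  J0 <- spectralDensityMatrix(sd, 0)
  rates <- numeric(dI)
  for (i in seq_len(dI)) {
    m <- mVals[i]
    ## secular dephasing: frequency fluctuation cg + m az
    rates[i] <- Re(J0[1, 1] + 2 * m * J0[1, 4] + m^2 * J0[4, 4])
    ## pseudosecular lifetime: golden-rule flips m -> k via ax Ix + ay Iy,
    ## double-sided PSD S(w) = 2 Re J(w), coupling (1/2) a . I per manifold
    for (k in seq_len(dI)) {
      if (k == i) next
      om <- eps[i] - eps[k]   # level gap within one electron manifold
      Xki <- I$Jx[k, i]; Yki <- I$Jy[k, i]
      S <- function(p, q) Re(spectralDensityMatrix(sd, om)[p, q] +
                               spectralDensityMatrix(sd, -om)[p, q])
      w <- (1 / 4) * (Mod(Xki)^2 * S(2, 2) + Mod(Yki)^2 * S(3, 3) +
                        2 * Re(Conj(Xki) * Yki) * S(2, 3))
      rates[i] <- rates[i] + w
    }
  }
  data.frame(mI = mVals, rate = rates)
}

## simple peak finder for absorption spectra: local maxima above a
## fraction of the global maximum
findPeaks <- function(spectrum, frac = 0.2) {
  y <- intensity(spectrum)
  x <- fieldAxis(spectrum)
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n] &
                 y[2:(n - 1)] > frac * max(y)) + 1L
  ## merge peaks closer than 0.05 mT
  if (length(idx) > 1) {
    keep <- c(TRUE, diff(x[idx]) > 0.05)
    idx <- idx[keep]
  }
  data.frame(fieldMt = x[idx], height = y[idx])
}

## synthesize a noiseless three-line first-derivative Voigt spectrum
synthSpectrum <- function(centers, lorFwhmMt, gaussFwhmMt, amps,
                          sweepMt = 12, nPoints = 4096) {
  x <- seq(-sweepMt / 2, sweepMt / 2, length.out = nPoints)
  y <- 0
  for (k in seq_along(centers))
    y <- y + amps[k] * voigtDerivative(x - centers[k], lorFwhmMt[k],
                                       gaussFwhmMt[k])
  esrSpectrum(x, y, mode = "first_derivative")
}
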