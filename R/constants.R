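## Physical constants (CODATA 2018, SI units)

#' Physical constants used throughout the package
#'
#' Bohr magneton, Planck constants and unit-conversion helpers. All internal
#' spin-interaction magnitudes are carried in angular frequency units (rad/s);
#' file formats and user-facing arguments use MHz, mT/uT and ns/ps as stated
#' in the respective function documentation.
#'
#' @format A named list with elements `muB` (J/T), `h` (J s), `hbar` (J s).
#' @export
physicalConstants <- list(
  muB  = 9.2740100783e-24,
  h    = 6.62607015e-34,
  hbar = 1.054571817e-34
)

#' Convert a magnetic-field interval to an angular frequency
#'
#' Uses the electron Zeeman relation `omega = gIso * muB * B / hbar`, the
#' conversion the modulation amplitude and field-axis mapping are built on.
#'
#' @param fieldT Field interval in tesla.
#' @param gIso Isotropic g value.
#' @return Angular frequency in rad/s.
#' @export
fieldToAngularFrequency <- function(fieldT, gIso) {
  gIso * physicalConstants$muB * fieldT / physicalConstants$hbar
}

#' @rdname fieldToAngularFrequency
#' @param omega Angular frequency in rad/s.
#' @return `angularFrequencyToField`: field interval in tesla.
#' @export
angularFrequencyToField <- function(omega, gIso) {
  omega * physicalConstants$hbar / (gIso * physicalConstants$muB)
}

#' Convert hyperfine values between MHz and field units
#'
#' Field-unit hyperfine couplings (gauss or millitesla) are converted to MHz
#' through `gIso * muB / h`; this is the conventional ESR convention for
#' quoting tensors measured on a field axis.
#'
#' @param value Numeric vector of couplings.
#' @param from,to One of `"MHz"`, `"mT"`, `"G"`.
#' @param gIso Isotropic g value used for field conversions.
#' @return Numeric vector in the target unit.
#' @export
convertHyperfine <- function(value, from = "MHz", to = "MHz", gIso = 2.0059) {
  units <- c("MHz", "mT", "G")
  from <- match.arg(from, units); to <- match.arg(to, units)
  ## to MHz first
  mhzPerT <- gIso * physicalConstants$muB / physicalConstants$h / 1e6
  inMHz <- switch(from,
    MHz = value,
    mT  = value * 1e-3 * mhzPerT,
    G   = value * 1e-4 * mhzPerT)
  switch(to,
    MHz = inMHz,
    mT  = inMHz / mhzPerT * 1e3,
    G   = inMHz / mhzPerT * 1e4)
}
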