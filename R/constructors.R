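#' Construct a SpinSystem
#'
#' @param nuclearSpin 1 (14N) or 0.5 (15N). May also be given as the isotope
#'   string `"14N"`/`"15N"`.
#' @param gPrincipal Three g-tensor principal values (PAS x, y, z). Defaults
#'   are typical nitroxide literature values.
#' @param aPrincipal Three hyperfine principal values in `aUnit`.
#' @param aUnit Unit of `aPrincipal`: `"MHz"` (default), `"mT"` or `"G"`.
#' @return A validated [SpinSystem-class] object.
#' @examples
#' ss <- spinSystem("14N")
#' gIso(ss)
#' @export
spinSystem <- function(nuclearSpin = 1,
                       gPrincipal = c(2.0083, 2.0061, 2.0022),
                       aPrincipal = c(17.4, 17.4, 98.0),
                       aUnit = "MHz") {
  if (is.character(nuclearSpin)) {
    nuclearSpin <- switch(nuclearSpin,
      "14N" = 1, "15N" = 0.5,
      stop("unsupported isotope label: ", nuclearSpin))
  }
  if (!nuclearSpin %in% c(0.5, 1))
    stop("nuclearSpin must be 1 (14N) or 1/2 (15N)")
  gI <- mean(gPrincipal)
  aPrincipal <- convertHyperfine(aPrincipal, from = aUnit, to = "MHz", gIso = gI)
  new("SpinSystem",
      nuclearSpin = nuclearSpin,
      gPrincipal = as.numeric(gPrincipal),
      aPrincipal = as.numeric(aPrincipal),
      isotopeLabel = if (nuclearSpin == 1) "14N" else "15N")
}

#' Rescale a 14N hyperfine tensor to 15N (opt-in helper)
#'
#' Multiplies the hyperfine principal values by the gyromagnetic ratio
#' magnitude |gamma(15N)/gamma(14N)| = 1.4027 and switches the nuclear spin
#' to 1/2. Supplying a measured 15N tensor directly is preferred; this helper
#' exists for quick estimates only.
#'
#' @param spec A [SpinSystem-class] with `nuclearSpin = 1`.
#' @return A 15N [SpinSystem-class].
#' @export
scaleTo15N <- function(spec) {
  stopifnot(is(spec, "SpinSystem"))
  if (spec@nuclearSpin != 1) stop("scaleTo15N expects a 14N system")
  spinSystem(0.5, spec@gPrincipal, spec@aPrincipal * 1.4027, aUnit = "MHz")
}

#' Construct a FieldConfig
#'
#' Either the static field or the microwave frequency may be given; the
#' other is filled in from the resonance condition `gIso muB B0 = h nu`.
#'
#' @param mwFrequency Microwave frequency in GHz (X band default 9.45).
#' @param B0 Static field in tesla; derived from `mwFrequency` when `NULL`.
#' @param gIso Isotropic g value used to resolve the resonance condition.
#' @return A [FieldConfig-class] object.
#' @export
fieldConfig <- function(mwFrequency = 9.45, B0 = NULL, gIso = 2.0055) {
  if (is.null(B0)) {
    B0 <- physicalConstants$h * mwFrequency * 1e9 /
      (gIso * physicalConstants$muB)
  }
  new("FieldConfig", B0 = B0, mwFrequencyGHz = mwFrequency)
}

#' Construct an OrientationTrajectory
#'
#' @param quaternions N x 4 matrix of unit quaternions (scalar-first),
#'   PAS-to-lab. Rows are sign-aligned automatically.
#' @param deltaPs Time step in picoseconds (default 1).
#' @param normalize Renormalise rows to unit length before validation.
#' @return An [OrientationTrajectory-class] object.
#' @export
orientationTrajectory <- function(quaternions, deltaPs = 1, normalize = FALSE) {
  q <- .asQuatMatrix(quaternions)
  if (normalize) {
    nrm <- sqrt(rowSums(q^2))
    off <- abs(nrm - 1) > 1e-12     # leave already-unit rows bit-identical
    if (any(off)) q[off, ] <- q[off, , drop = FALSE] / nrm[off]
  }
  q <- quatAlignSigns(q)
  colnames(q) <- c("w", "x", "y", "z")
  new("OrientationTrajectory", quaternions = q, deltaPs = deltaPs)
}

#' Construct a DecomposedTrajectory
#' @param global,internal [OrientationTrajectory-class] parts Q(t) and r(t).
#' @return A [DecomposedTrajectory-class] object.
#' @export
decomposedTrajectory <- function(global, internal) {
  new("DecomposedTrajectory", global = global, internal = internal)
}

#' Construct a CorrelationFunction
#' @param lagPs Lag axis, ps.
#' @param values Correlation values.
#' @param normalized Logical.
#' @return A [CorrelationFunction-class] object.
#' @export
correlationFunction <- function(lagPs, values, normalized = TRUE) {
  new("CorrelationFunction", lagPs = lagPs, values = values,
      normalized = normalized)
}

#' Construct an AngleSeries
#' @param values Dihedral angles in degrees; wrapped into (-180, 180].
#' @param deltaPs Frame spacing, ps.
#' @param label Dihedral label, e.g. `"chi1"`.
#' @return An [AngleSeries-class] object.
#' @export
angleSeries <- function(values, deltaPs = 1, label = "chi") {
  v <- ((values + 180) %% 360)
  v <- ifelse(v == 0, 180, v - 180)
  ## map -180 to +180 boundary of the half-open interval
  v <- ifelse(v == -180, 180, v)
  new("AngleSeries", values = v, deltaPs = deltaPs, label = label)
}

#' Construct a BroadeningModel
#'
#' Defaults are the collective-fit values for air-equilibrated aqueous
#' samples: oxygen T2 of 0.83 us (13.5 uT Lorentzian FWHH) and a 126 uT
#' Gaussian from field inhomogeneity plus unresolved couplings.
#'
#' @param t2O2Us Oxygen-induced electron T2, microseconds (Inf disables).
#' @param gaussianFwhmUt Gaussian FWHH, microtesla (0 disables).
#' @return A [BroadeningModel-class] object.
#' @export
broadeningModel <- function(t2O2Us = 0.83, gaussianFwhmUt = 126) {
  new("BroadeningModel", t2O2Us = t2O2Us, gaussianFwhmUt = gaussianFwhmUt)
}

#' Construct a ModulationConfig
#' @param hmMt Peak-to-peak modulation amplitude, mT (default 0.05).
#' @return A [ModulationConfig-class] object.
#' @export
modulationConfig <- function(hmMt = 0.05) {
  new("ModulationConfig", hmMt = hmMt)
}

#' Construct an EsrSpectrum
#' @param fieldMt Field-offset axis, mT.
#' @param intensity Intensities.
#' @param mode `"first_derivative"` or `"absorption"`.
#' @param meta Named list of provenance entries.
#' @return An [EsrSpectrum-class] object.
#' @export
esrSpectrum <- function(fieldMt, intensity, mode = "first_derivative",
                        meta = list()) {
  new("EsrSpectrum", fieldMt = as.numeric(fieldMt),
      intensity = as.numeric(intensity), mode = mode, meta = meta)
}
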