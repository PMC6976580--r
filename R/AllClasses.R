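#' @import methods
NULL

## ---------------------------------------------------------------------------
## Spin system and field configuration
## ---------------------------------------------------------------------------

#' SpinSystem: electron-nuclear spin pair of a nitroxide
#'
#' Holds the g-tensor and hyperfine-tensor principal values of the radical
#' together with the nuclear spin quantum number: I = 1 for a 14N nitroxide
#' (three-line spectrum) or I = 1/2 for a 15N-enriched label (doublet). The
#' anisotropic parts `gAniso(x)` / `aAniso(x)` are the traceless principal-
#' axes-system (PAS) tensors obtained by subtracting the isotropic means.
#'
#' @slot nuclearSpin Nuclear spin quantum number, 1 or 0.5.
#' @slot gPrincipal Three dimensionless g principal values (x, y, z of PAS).
#' @slot aPrincipal Three hyperfine principal values in MHz.
#' @slot isotopeLabel `"14N"` or `"15N"`.
#' @export
setClass("SpinSystem", representation(
  nuclearSpin = "numeric",
  gPrincipal  = "numeric",
  aPrincipal  = "numeric",
  isotopeLabel = "character"))

setValidity("SpinSystem", function(object) {
  msg <- character()
  if (!object@nuclearSpin %in% c(0.5, 1))
    msg <- c(msg, "nuclearSpin must be 1 (14N) or 0.5 (15N)")
  if (length(object@gPrincipal) != 3L || any(!is.finite(object@gPrincipal)))
    msg <- c(msg, "gPrincipal must be three finite values")
  if (length(object@aPrincipal) != 3L || any(!is.finite(object@aPrincipal)))
    msg <- c(msg, "aPrincipal must be three finite values (MHz)")
  expected <- if (isTRUE(object@nuclearSpin == 1)) "14N" else "15N"
  if (length(object@isotopeLabel) != 1L || object@isotopeLabel != expected)
    msg <- c(msg, sprintf("isotopeLabel must be '%s' for nuclearSpin = %s",
                          expected, format(object@nuclearSpin)))
  if (length(msg)) msg else TRUE
})

#' FieldConfig: static field and microwave carrier
#'
#' @slot B0 Static magnetic field in tesla (laboratory z axis).
#' @slot mwFrequencyGHz Microwave carrier frequency in GHz.
#' @export
setClass("FieldConfig", representation(
  B0 = "numeric",
  mwFrequencyGHz = "numeric"))

setValidity("FieldConfig", function(object) {
  if (object@B0 <= 0) return("B0 must be positive")
  if (object@mwFrequencyGHz <= 0) return("mwFrequency must be positive")
  TRUE
})

#' OperatorSet: spin operators on the composite electron-nuclear space
#'
#' Matrices for Sx, Sy, Sz, Sp, Sm, Ix, Iy, Iz, Ip, Im and the identity on
#' the space of dimension `2 * (2I + 1)` (6 for 14N, 4 for 15N).
#'
#' @slot operators Named list of complex matrices.
#' @slot dimension Integer dimension of the composite Hilbert space.
#' @slot nuclearSpin The nuclear spin quantum number.
#' @export
setClass("OperatorSet", representation(
  operators = "list",
  dimension = "integer",
  nuclearSpin = "numeric"))

setValidity("OperatorSet", function(object) {
  need <- c("Sx", "Sy", "Sz", "Sp", "Sm", "Ix", "Iy", "Iz", "Ip", "Im", "E")
  if (!all(need %in% names(object@operators)))
    return(paste("missing operators:",
                 paste(setdiff(need, names(object@operators)), collapse = ", ")))
  d <- object@dimension
  if (d != 2L * (2L * object@nuclearSpin + 1L))
    return("dimension must equal 2*(2I+1)")
  ok <- all(vapply(object@operators, function(m)
    all(dim(m) == c(d, d)), logical(1)))
  if (!ok) return("all operators must be dimension x dimension matrices")
  TRUE
})

## ---------------------------------------------------------------------------
## Trajectories and correlation functions
## ---------------------------------------------------------------------------

#' OrientationTrajectory: uniform-step sequence of PAS-to-lab rotations
#'
#' Unit quaternions (scalar-first), one row per frame, sampled every
#' `deltaPs` picoseconds. Consecutive rows are sign-aligned on construction.
#'
#' @slot quaternions N x 4 numeric matrix of unit quaternions.
#' @slot deltaPs Sampling step in picoseconds.
#' @export
setClass("OrientationTrajectory", representation(
  quaternions = "matrix",
  deltaPs = "numeric"))

setValidity("OrientationTrajectory", function(object) {
  q <- object@quaternions
  msg <- character()
  if (ncol(q) != 4L) msg <- c(msg, "quaternions must have 4 columns")
  if (nrow(q) < 2L) msg <- c(msg, "at least 2 frames required")
  if (object@deltaPs <= 0) msg <- c(msg, "deltaPs must be positive")
  norms <- sqrt(rowSums(q^2))
  if (any(abs(norms - 1) > 1e-9))
    msg <- c(msg, "quaternions must be unit norm within 1e-9")
  if (nrow(q) >= 2L) {
    dots <- rowSums(q[-nrow(q), , drop = FALSE] * q[-1, , drop = FALSE])
    if (any(dots < 0))
      msg <- c(msg, "consecutive quaternions must be sign-aligned")
  }
  if (length(msg)) msg else TRUE
})

#' DecomposedTrajectory: global tumbling and internal label motion
#'
#' The full PAS-to-lab rotation factorises as `R(t) = Q(t) o r(t)` with
#' `Q(t)` the molecule-to-lab (tumbling) part and `r(t)` the PAS-to-molecule
#' (internal) part; both share the time step and length.
#'
#' @slot global `OrientationTrajectory` Q(t), molecule to lab.
#' @slot internal `OrientationTrajectory` r(t), PAS to molecule.
#' @export
setClass("DecomposedTrajectory", representation(
  global = "OrientationTrajectory",
  internal = "OrientationTrajectory"))

setValidity("DecomposedTrajectory", function(object) {
  gq <- object@global@quaternions; iq <- object@internal@quaternions
  if (nrow(gq) != nrow(iq)) return("global and internal must share length")
  if (object@global@deltaPs != object@internal@deltaPs)
    return("global and internal must share the time step")
  TRUE
})

#' CorrelationFunction: lag-resolved time correlation
#'
#' @slot lagPs Lag axis in picoseconds, strictly increasing from 0.
#' @slot values Correlation values (dimensionless).
#' @slot normalized Logical; normalized functions satisfy C(0) = 1.
#' @export
setClass("CorrelationFunction", representation(
  lagPs = "numeric",
  values = "numeric",
  normalized = "logical"))

setValidity("CorrelationFunction", function(object) {
  if (length(object@lagPs) != length(object@values))
    return("lag axis and values must have equal length")
  if (any(diff(object@lagPs) <= 0)) return("lag axis must be strictly increasing")
  if (isTRUE(object@normalized) && abs(object@values[1] - 1) > 1e-6)
    return("normalized correlation must satisfy C(0) = 1")
  TRUE
})

#' AngleSeries: per-frame dihedral angle trace
#'
#' Values in degrees on the periodic interval (-180, 180]; `label` names the
#' rotatable bond (chi1..chi5 of the R1 side chain).
#'
#' @slot values Angles in degrees.
#' @slot deltaPs Frame spacing in picoseconds.
#' @slot label Dihedral label.
#' @export
setClass("AngleSeries", representation(
  values = "numeric",
  deltaPs = "numeric",
  label = "character"))

setValidity("AngleSeries", function(object) {
  if (any(object@values <= -180 | object@values > 180))
    return("angles must lie in (-180, 180] degrees")
  if (object@deltaPs <= 0) return("deltaPs must be positive")
  TRUE
})

#' MotionModel: parameterised synthetic motion generator
#'
#' @slot kind One of `"isotropic_diffusion"`, `"axial_diffusion"`,
#'   `"cone_diffusion"`, `"discrete_jump"`, `"multistate_exchange"`.
#' @slot parameters Named list of model parameters.
#' @slot seed Integer RNG seed recorded with the model.
#' @export
setClass("MotionModel", representation(
  kind = "character",
  parameters = "list",
  seed = "integer"))

setValidity("MotionModel", function(object) {
  kinds <- c("isotropic_diffusion", "axial_diffusion", "cone_diffusion",
             "discrete_jump", "multistate_exchange")
  if (!object@kind %in% kinds)
    return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
  TRUE
})

## ---------------------------------------------------------------------------
## Signals and spectra
## ---------------------------------------------------------------------------

#' Fid: complex free induction decay
#'
#' Transverse-magnetisation trace `Tr{S+ sigma(tau)}` on a uniform time axis,
#' detected in the frame rotating at the isotropic electron Zeeman frequency.
#'
#' @slot timesPs Uniform time axis in picoseconds, starting at 0.
#' @slot values Complex FID values.
#' @slot carrier Description of the detection frame.
#' @export
setClass("Fid", representation(
  timesPs = "numeric",
  values = "complex",
  carrier = "character"))

setValidity("Fid", function(object) {
  if (length(object@timesPs) != length(object@values))
    return("time axis and values must match")
  if (length(object@timesPs) < 2L) return("FID needs at least 2 points")
  dt <- diff(object@timesPs)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) return("time axis must be uniform")
  TRUE
})

#' BroadeningModel: oxygen Lorentzian and inhomogeneous Gaussian terms
#'
#' Extra line broadening applied on top of the propagation result: a
#' Lorentzian from collisions with dissolved paramagnetic O2 (parameterised
#' by the electron T2) and a Gaussian from static field inhomogeneity plus
#' unresolved hyperfine couplings. Zero disables a term.
#'
#' @slot t2O2Us Oxygen-induced electron T2 in microseconds (Inf disables).
#' @slot gaussianFwhmUt Gaussian full width at half height in microtesla.
#' @export
setClass("BroadeningModel", representation(
  t2O2Us = "numeric",
  gaussianFwhmUt = "numeric"))

setValidity("BroadeningModel", function(object) {
  if (object@t2O2Us <= 0) return("t2O2Us must be positive (Inf disables)")
  if (object@gaussianFwhmUt < 0) return("gaussianFwhmUt must be non-negative")
  TRUE
})

#' ModulationConfig: field-modulation detection settings
#'
#' @slot hmMt Peak-to-peak modulation field amplitude in millitesla.
#' @export
setClass("ModulationConfig", representation(hmMt = "numeric"))

setValidity("ModulationConfig", function(object) {
  if (object@hmMt <= 0) return("modulation amplitude must be positive")
  TRUE
})

#' EsrSpectrum: field-domain lineshape
#'
#' Intensity on a strictly increasing field-offset axis (mT from the sweep
#' centre), either as the modulation-detected first derivative or as the
#' absorption profile.
#'
#' @slot fieldMt Field-offset axis, mT.
#' @slot intensity Intensity, arbitrary units.
#' @slot mode `"first_derivative"` or `"absorption"`.
#' @slot meta Named list of provenance (B0, Hm, broadening, ...).
#' @export
setClass("EsrSpectrum", representation(
  fieldMt = "numeric",
  intensity = "numeric",
  mode = "character",
  meta = "list"))

setValidity("EsrSpectrum", function(object) {
  if (length(object@fieldMt) != length(object@intensity))
    return("axis and intensity must match")
  if (any(diff(object@fieldMt) <= 0)) return("field axis must be strictly increasing")
  if (!object@mode %in% c("first_derivative", "absorption"))
    return("mode must be 'first_derivative' or 'absorption'")
  TRUE
})

## ---------------------------------------------------------------------------
## Redfield machinery
## ---------------------------------------------------------------------------

#' SpectralDensitySet: trajectory-derived correlation functions and J(omega)
#'
#' Auto- and cross-correlations of the lab-frame secular coupling
#' coefficients of the anisotropic Zeeman and hyperfine interactions,
#' together with the one-sided spectral-density interpolants used by the
#' relaxation supermatrix. Components are ordered (g, ax, ay, az): the
#' anisotropic-Zeeman frequency shift and the three hyperfine field
#' components along the laboratory z row of the coupling tensor.
#'
#' @slot lagPs Lag axis of the sampled correlations, ps.
#' @slot corr 4 x 4 x nLag array of correlations, (rad/s)^2.
#' @slot meanCoef Mean secular coefficients (rad/s), length 4; carries the
#'   static (motionally averaged) Hamiltonian.
#' @slot tailTauPs Fitted exponential tail time constant, ps.
#' @slot tailAmp Fitted tail amplitudes at the last sampled lag, 4 x 4.
#' @slot tauCPs Effective correlation time (ps) of the summed decay.
#' @slot decays Logical validity flag: FALSE when correlations do not decay.
#' @export
setClass("SpectralDensitySet", representation(
  lagPs = "numeric",
  corr = "array",
  meanCoef = "numeric",
  tailTauPs = "numeric",
  tailAmp = "matrix",
  tauCPs = "numeric",
  decays = "logical"))

#' RedfieldModel: coherent plus relaxation superoperator
#'
#' Liouvillian acting on the electron single-quantum coherence block (the
#' only block that contributes to the CW lineshape under the secular
#' "Redfield kite" structure of this spin system), assembled from the static
#' Hamiltonian and the trajectory spectral densities.
#'
#' @slot liouvillian Complex (2I+1)^2 square matrix.
#' @slot dimension Nuclear sub-space dimension 2I+1.
#' @slot spec The `SpinSystem` used.
#' @slot includeCrossCorrelations Logical toggle for g x A cross terms.
#' @slot detect Complex detection vector.
#' @slot start Complex initial-coherence vector.
#' @export
setClass("RedfieldModel", representation(
  liouvillian = "matrix",
  dimension = "integer",
  spec = "SpinSystem",
  includeCrossCorrelations = "logical",
  detect = "complex",
  start = "complex"))
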