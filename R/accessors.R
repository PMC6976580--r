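## Accessor generics and methods; slot access stays internal to the package.

#' @rdname spinSystemAccessors
#' @export
setGeneric("gIso", function(x) standardGeneric("gIso"))
#' @rdname spinSystemAccessors
#' @export
setGeneric("aIso", function(x) standardGeneric("aIso"))
#' @rdname spinSystemAccessors
#' @export
setGeneric("gAniso", function(x) standardGeneric("gAniso"))
#' @rdname spinSystemAccessors
#' @export
setGeneric("aAniso", function(x) standardGeneric("aAniso"))
#' @rdname spinSystemAccessors
#' @export
setGeneric("nuclearSpin", function(x) standardGeneric("nuclearSpin"))

#' Accessors for SpinSystem objects
#'
#' `gIso`/`aIso` return isotropic means (`aIso` in MHz); `gAniso`/`aAniso`
#' return the traceless diagonal PAS tensors `diag(principal) - iso * I`.
#'
#' @param x A [SpinSystem-class].
#' @name spinSystemAccessors
#' @aliases gIso,SpinSystem-method aIso,SpinSystem-method
#'   gAniso,SpinSystem-method aAniso,SpinSystem-method
#'   nuclearSpin,SpinSystem-method
NULL

setMethod("gIso", "SpinSystem", function(x) mean(x@gPrincipal))
setMethod("aIso", "SpinSystem", function(x) mean(x@aPrincipal))
setMethod("gAniso", "SpinSystem", function(x)
  diag(x@gPrincipal - mean(x@gPrincipal)))
setMethod("aAniso", "SpinSystem", function(x)
  diag(x@aPrincipal - mean(x@aPrincipal)))
setMethod("nuclearSpin", "SpinSystem", function(x) x@nuclearSpin)

#' @rdname trajectoryAccessors
#' @export
setGeneric("trajectoryQuaternions",
           function(x) standardGeneric("trajectoryQuaternions"))
#' @rdname trajectoryAccessors
#' @export
setGeneric("trajectoryDelta", function(x) standardGeneric("trajectoryDelta"))
#' @rdname trajectoryAccessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname trajectoryAccessors
#' @export
setGeneric("globalPart", function(x) standardGeneric("globalPart"))
#' @rdname trajectoryAccessors
#' @export
setGeneric("internalPart", function(x) standardGeneric("internalPart"))

#' Accessors for trajectory objects
#'
#' @param x An [OrientationTrajectory-class] or
#'   [DecomposedTrajectory-class].
#' @name trajectoryAccessors
#' @aliases trajectoryQuaternions,OrientationTrajectory-method
#'   trajectoryDelta,OrientationTrajectory-method
#'   nFrames,OrientationTrajectory-method
#'   globalPart,DecomposedTrajectory-method
#'   internalPart,DecomposedTrajectory-method
#'   nFrames,DecomposedTrajectory-method
#'   trajectoryDelta,DecomposedTrajectory-method
NULL

setMethod("trajectoryQuaternions", "OrientationTrajectory",
          function(x) x@quaternions)
setMethod("trajectoryDelta", "OrientationTrajectory", function(x) x@deltaPs)
setMethod("nFrames", "OrientationTrajectory",
          function(x) nrow(x@quaternions))
setMethod("globalPart", "DecomposedTrajectory", function(x) x@global)
setMethod("internalPart", "DecomposedTrajectory", function(x) x@internal)
setMethod("nFrames", "DecomposedTrajectory",
          function(x) nrow(x@global@quaternions))
setMethod("trajectoryDelta", "DecomposedTrajectory",
          function(x) x@global@deltaPs)

#' @rdname signalAccessors
#' @export
setGeneric("fidTimes", function(x) standardGeneric("fidTimes"))
#' @rdname signalAccessors
#' @export
setGeneric("fidValues", function(x) standardGeneric("fidValues"))
#' @rdname signalAccessors
#' @export
setGeneric("fieldAxis", function(x) standardGeneric("fieldAxis"))
#' @rdname signalAccessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @rdname signalAccessors
#' @export
setGeneric("spectrumMode", function(x) standardGeneric("spectrumMode"))

#' Accessors for FID and spectrum objects
#'
#' @param x A [Fid-class] or [EsrSpectrum-class].
#' @name signalAccessors
#' @aliases fidTimes,Fid-method fidValues,Fid-method
#'   fieldAxis,EsrSpectrum-method intensity,EsrSpectrum-method
#'   spectrumMode,EsrSpectrum-method
NULL

setMethod("fidTimes", "Fid", function(x) x@timesPs)
setMethod("fidValues", "Fid", function(x) x@values)
setMethod("fieldAxis", "EsrSpectrum", function(x) x@fieldMt)
setMethod("intensity", "EsrSpectrum", function(x) x@intensity)
setMethod("spectrumMode", "EsrSpectrum", function(x) x@mode)

## -- show methods ----------------------------------------------------------

setMethod("show", "SpinSystem", function(object) {
  cat(sprintf("SpinSystem: %s (I = %s)\n", object@isotopeLabel,
              format(object@nuclearSpin)))
  cat(sprintf("  g principal: %s  (gIso %.5f)\n",
              paste(format(object@gPrincipal, digits = 6), collapse = ", "),
              mean(object@gPrincipal)))
  cat(sprintf("  A principal: %s MHz  (Aiso %.2f MHz)\n",
              paste(format(object@aPrincipal, digits = 4), collapse = ", "),
              mean(object@aPrincipal)))
})

setMethod("show", "FieldConfig", function(object) {
  cat(sprintf("FieldConfig: B0 = %.4f T, mw = %.3f GHz\n",
              object@B0, object@mwFrequencyGHz))
})

setMethod("show", "OrientationTrajectory", function(object) {
  n <- nrow(object@quaternions)
  cat(sprintf("OrientationTrajectory: %d frames, delta = %g ps (%.3f ns)\n",
              n, object@deltaPs, n * object@deltaPs / 1000))
})

setMethod("show", "DecomposedTrajectory", function(object) {
  cat("DecomposedTrajectory (R = Q o r)\n  global:   ")
  show(object@global)
  cat("  internal: ")
  show(object@internal)
})

setMethod("show", "Fid", function(object) {
  cat(sprintf("Fid: %d points, dt = %g ps, span %.1f ns [%s]\n",
              length(object@timesPs), diff(object@timesPs[1:2]),
              max(object@timesPs) / 1000, object@carrier))
})

setMethod("show", "EsrSpectrum", function(object) {
  cat(sprintf("EsrSpectrum (%s): %d points, field %.2f .. %.2f mT\n",
              object@mode, length(object@fieldMt), min(object@fieldMt),
              max(object@fieldMt)))
})

setMethod("show", "CorrelationFunction", function(object) {
  cat(sprintf("CorrelationFunction: %d lags, 0 .. %g ps%s\n",
              length(object@lagPs), max(object@lagPs),
              if (object@normalized) " (normalized)" else ""))
})

setMethod("show", "MotionModel", function(object) {
  cat(sprintf("MotionModel '%s' (seed %d)\n", object@kind, object@seed))
  p <- object@parameters
  for (nm in names(p))
    cat(sprintf("  %s: %s\n", nm, paste(format(unlist(p[[nm]])), collapse = " ")))
})

setMethod("show", "OperatorSet", function(object) {
  cat(sprintf("OperatorSet: I = %s, dimension %d\n",
              format(object@nuclearSpin), object@dimension))
})

setMethod("show", "RedfieldModel", function(object) {
  cat(sprintf(
    "RedfieldModel: SQ block %d x %d, cross-correlations %s\n",
    object@dimension^2, object@dimension^2,
    if (object@includeCrossCorrelations) "on" else "off"))
})
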