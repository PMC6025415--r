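#' @include AllClasses.R
NULL

#' Accessors for EEMGrid and AbsorptionSpectrum
#'
#' Slot access goes through accessors; the slots themselves are not part
#' of the supported interface.
#'
#' @param object an [EEMGrid-class], [AbsorptionSpectrum-class],
#'   [FRIResult-class] or [RiskResult-class] object
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("excitation", function(object) standardGeneric("excitation"))
#' @rdname accessors
#' @export
setGeneric("emission", function(object) standardGeneric("emission"))
#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("excisedMask", function(object) standardGeneric("excisedMask"))
#' @rdname accessors
#' @export
setGeneric("sampleID", function(object) standardGeneric("sampleID"))
#' @rdname accessors
#' @export
setGeneric("correctionsApplied",
           function(object) standardGeneric("correctionsApplied"))
#' @rdname accessors
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))
#' @rdname accessors
#' @export
setGeneric("opticalDensity",
           function(object) standardGeneric("opticalDensity"))
#' @rdname accessors
#' @export
setGeneric("pathLength", function(object) standardGeneric("pathLength"))
#' @rdname accessors
#' @export
setGeneric("phi", function(object) standardGeneric("phi"))
#' @rdname accessors
#' @export
setGeneric("phiTotal", function(object) standardGeneric("phiTotal"))
#' @rdname accessors
#' @export
setGeneric("regionShares", function(object) standardGeneric("regionShares"))
#' @rdname accessors
#' @export
setGeneric("alloVolume", function(object) standardGeneric("alloVolume"))
#' @rdname accessors
#' @export
setGeneric("autoVolume", function(object) standardGeneric("autoVolume"))
#' @rdname accessors
#' @export
setGeneric("unassignedVolume",
           function(object) standardGeneric("unassignedVolume"))
#' @rdname accessors
#' @export
setGeneric("hazardQuotients",
           function(object) standardGeneric("hazardQuotients"))
#' @rdname accessors
#' @export
setGeneric("averageDailyDoses",
           function(object) standardGeneric("averageDailyDoses"))

setMethod("excitation", "EEMGrid", function(object) object@excitation)
setMethod("emission", "EEMGrid", function(object) object@emission)
setMethod("intensity", "EEMGrid", function(object) object@intensity)
setMethod("excisedMask", "EEMGrid", function(object) object@mask)
setMethod("sampleID", "EEMGrid", function(object) object@sampleID)
setMethod("correctionsApplied", "EEMGrid",
          function(object) object@correctionsApplied)

setMethod("wavelength", "AbsorptionSpectrum",
          function(object) object@wavelength)
setMethod("opticalDensity", "AbsorptionSpectrum",
          function(object) object@opticalDensity)
setMethod("pathLength", "AbsorptionSpectrum",
          function(object) object@pathLength)
setMethod("sampleID", "AbsorptionSpectrum", function(object) object@sampleID)

setMethod("phi", "FRIResult", function(object) object@phi)
setMethod("phiTotal", "FRIResult", function(object) object@phiTotal)
setMethod("regionShares", "FRIResult", function(object) object@shares)
setMethod("alloVolume", "FRIResult", function(object) object@allo)
setMethod("autoVolume", "FRIResult", function(object) object@auto)
setMethod("unassignedVolume", "FRIResult", function(object) object@unassigned)
setMethod("sampleID", "FRIResult", function(object) object@sampleID)

setMethod("hazardQuotients", "RiskResult", function(object) object@hq)
setMethod("averageDailyDoses", "RiskResult", function(object) object@add)

#' @rdname accessors
#' @export
setGeneric("hazardIndexValue",
           function(object) standardGeneric("hazardIndexValue"))
setMethod("hazardIndexValue", "RiskResult", function(object) object@hi)

#' @rdname accessors
#' @export
setGeneric("riskClassification",
           function(object) standardGeneric("riskClassification"))
setMethod("riskClassification", "RiskResult",
          function(object) object@classification)

setMethod("show", "EEMGrid", function(object) {
  ex <- object@excitation
  em <- object@emission
  cat("EEMGrid", if (nzchar(object@sampleID))
        paste0("'", object@sampleID, "'") else "", "\n")
  cat(sprintf("  excitation: %d points, %g-%g nm\n",
              length(ex), min(ex), max(ex)))
  cat(sprintf("  emission:   %d points, %g-%g nm\n",
              length(em), min(em), max(em)))
  cat(sprintf("  corrections: %s\n",
              if (length(object@correctionsApplied))
                paste(object@correctionsApplied, collapse = ", ")
              else "none"))
  if (any(object@mask)) {
    cat(sprintf("  excised cells: %d\n", sum(object@mask)))
  }
  invisible(NULL)
})

setMethod("show", "AbsorptionSpectrum", function(object) {
  wl <- object@wavelength
  cat("AbsorptionSpectrum", if (nzchar(object@sampleID))
        paste0("'", object@sampleID, "'") else "", "\n")
  cat(sprintf("  %d wavelengths, %g-%g nm; path %g m\n",
              length(wl), min(wl), max(wl), object@pathLength))
  invisible(NULL)
})

setMethod("show", "FRIResult", function(object) {
  cat("FRIResult", if (nzchar(object@sampleID))
        paste0("'", object@sampleID, "'") else "", "\n")
  cat("  Phi_i (intensity*nm^2):\n")
  print(signif(object@phi, 5))
  cat(sprintf("  Phi_T = %.5g; allochthonous (R3+R5) share = %.3f\n",
              object@phiTotal,
              if (object@phiTotal > 0) object@allo / object@phiTotal
              else NA_real_))
  invisible(NULL)
})

setMethod("show", "RiskResult", function(object) {
  cat("RiskResult\n  ADD (mg/kg/day):\n")
  print(signif(object@add, 4))
  cat("  HQ:\n")
  print(signif(object@hq, 4))
  cat(sprintf("  HI = %.4g (%s); carcinogenic: %s\n",
              object@hi, object@classification, object@tier))
  invisible(NULL)
})
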