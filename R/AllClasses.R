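#' @import methods
NULL

#' EEMGrid: a single-sample excitation-emission matrix
#'
#' Container for one fluorescence excitation-emission matrix (EEM):
#' fluorescence intensity \code{I(lambda_ex, lambda_em)} measured on a
#' rectangular grid of excitation and emission wavelengths. The
#' conventional acquisition grid is excitation 220-450 nm in 5 nm steps
#' and emission 250-600 nm in 1 nm steps, but any strictly increasing
#' axes are accepted. A logical \code{mask} marks cells that have been
#' excised (e.g. scatter bands zeroed rather than interpolated) so that
#' downstream code can distinguish a true zero from a removed cell.
#'
#' @slot excitation numeric, strictly increasing excitation wavelengths (nm)
#' @slot emission numeric, strictly increasing emission wavelengths (nm)
#' @slot intensity numeric matrix, rows = excitation, columns = emission,
#'   in instrument fluorescence units (the pipeline is unit-agnostic)
#' @slot mask logical matrix of the same shape; TRUE marks excised cells
#' @slot sampleID character scalar
#' @slot correctionsApplied character vector, subset of
#'   \code{c("blank", "scatter", "inner_filter")}
#'
#' @seealso [readEEM()], [subtractBlank()], [friComponents()]
#' @export
setClass("EEMGrid",
  representation(
    excitation = "numeric",
    emission = "numeric",
    intensity = "matrix",
    mask = "matrix",
    sampleID = "character",
    correctionsApplied = "character"
  )
)

.validEEMGrid <- function(object) {
  msg <- character()
  ex <- object@excitation
  em <- object@emission
  I <- object@intensity
  if (length(ex) < 1L || any(diff(ex) <= 0)) {
    msg <- c(msg, "excitation wavelengths must be strictly increasing")
  }
  if (length(em) < 1L || any(diff(em) <= 0)) {
    msg <- c(msg, "emission wavelengths must be strictly increasing")
  }
  if (!all(dim(I) == c(length(ex), length(em)))) {
    msg <- c(msg, sprintf(
      "intensity must be %d x %d (excitation x emission), got %d x %d",
      length(ex), length(em), nrow(I), ncol(I)
    ))
  }
  if (!all(dim(object@mask) == dim(I))) {
    msg <- c(msg, "mask must have the same dimensions as intensity")
  }
  if (any(!is.finite(I[!object@mask]))) {
    msg <- c(msg, "unmasked intensities must be finite")
  }
  unknown <- setdiff(object@correctionsApplied,
                     c("blank", "scatter", "inner_filter"))
  if (length(unknown)) {
    msg <- c(msg, paste0("unknown corrections: ",
                         paste(unknown, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}
setValidity("EEMGrid", .validEEMGrid)

#' Construct an EEMGrid
#'
#' @param excitation numeric excitation axis (nm), strictly increasing
#' @param emission numeric emission axis (nm), strictly increasing
#' @param intensity matrix of intensities, excitation in rows
#' @param sampleID sample identifier
#' @param correctionsApplied corrections already applied to the matrix
#' @param mask optional logical matrix flagging excised cells
#' @return an [EEMGrid-class] object
#' @examples
#' eem <- EEMGrid(seq(220, 450, 5), 250:600,
#'                matrix(1, 47, 351), sampleID = "demo")
#' @export
EEMGrid <- function(excitation, emission, intensity,
                    sampleID = "", correctionsApplied = character(),
                    mask = NULL) {
  intensity <- as.matrix(intensity)
  dimnames(intensity) <- NULL
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(intensity), ncol(intensity))
  }
  new("EEMGrid",
      excitation = as.numeric(excitation),
      emission = as.numeric(emission),
      intensity = intensity, mask = mask,
      sampleID = as.character(sampleID),
      correctionsApplied = correctionsApplied)
}

#' AbsorptionSpectrum: a UV-Vis optical density spectrum
#'
#' Optical density (decadic absorbance) versus wavelength for one water
#' sample, measured against a blank in a cuvette of known path length
#' (default 0.01 m, i.e. 1 cm). Wavelengths are expected inside 200-800
#' nm and must be strictly increasing.
#'
#' @slot wavelength numeric, strictly increasing wavelengths (nm)
#' @slot opticalDensity numeric, unitless OD values
#' @slot pathLength numeric scalar, cuvette path length in metres
#' @slot sampleID character scalar
#' @seealso [napierianAbsorption()], [readAbsorbance()]
#' @export
setClass("AbsorptionSpectrum",
  representation(
    wavelength = "numeric",
    opticalDensity = "numeric",
    pathLength = "numeric",
    sampleID = "character"
  )
)

.validAbsorptionSpectrum <- function(object) {
  msg <- character()
  wl <- object@wavelength
  if (length(wl) < 1L || any(diff(wl) <= 0)) {
    msg <- c(msg, "wavelengths must be strictly increasing (no duplicates)")
  }
  if (any(wl < 200 - 1e-6) || any(wl > 800 + 1e-6)) {
    msg <- c(msg, "wavelengths must lie within 200-800 nm")
  }
  if (length(object@opticalDensity) != length(wl)) {
    msg <- c(msg, "opticalDensity must match wavelength length")
  }
  if (any(!is.finite(object@opticalDensity))) {
    msg <- c(msg, "optical density values must be finite")
  }
  if (length(object@pathLength) != 1L || object@pathLength <= 0) {
    msg <- c(msg, "pathLength must be a single positive number (metres)")
  }
  if (length(msg)) msg else TRUE
}
setValidity("AbsorptionSpectrum", .validAbsorptionSpectrum)

#' Construct an AbsorptionSpectrum
#'
#' @param wavelength numeric wavelengths (nm), strictly increasing
#' @param opticalDensity numeric OD values (unitless)
#' @param pathLength cuvette path length in metres (default 0.01 = 1 cm)
#' @param sampleID sample identifier
#' @return an [AbsorptionSpectrum-class] object
#' @examples
#' AbsorptionSpectrum(250:600, rep(0.05, 351))
#' @export
AbsorptionSpectrum <- function(wavelength, opticalDensity,
                               pathLength = 0.01, sampleID = "") {
  new("AbsorptionSpectrum",
      wavelength = as.numeric(wavelength),
      opticalDensity = as.numeric(opticalDensity),
      pathLength = as.numeric(pathLength),
      sampleID = as.character(sampleID))
}

#' FRIResult: fluorescence regional integration summary
#'
#' Integrated volumes beneath an EEM for the five conventional regions
#' (tyrosine-like R1, tryptophan-like R2, fulvic-like R3, microbial
#' protein-like R4, humic-like R5), their total, the per-region shares,
#' the allochthonous (R3+R5) and autochthonous (R1+R2+R4) sums, and the
#' volume over grid cells assigned to no region (emission above 550 nm
#' or excitation above 400 nm on the default grid). Volumes are in
#' intensity x nm^2 (one 5 nm excitation step times one 1 nm emission
#' step per grid cell on the default axes).
#'
#' @slot phi named numeric of length 5, regional volumes
#' @slot phiTotal numeric scalar, sum of the five volumes
#' @slot shares named numeric of length 5, phi / phiTotal (NA when
#'   phiTotal is 0)
#' @slot allo numeric scalar, phi3 + phi5
#' @slot auto numeric scalar, phi1 + phi2 + phi4
#' @slot unassigned numeric scalar, volume outside all five regions
#' @slot sampleID character scalar
#' @seealso [friComponents()]
#' @export
setClass("FRIResult",
  representation(
    phi = "numeric",
    phiTotal = "numeric",
    shares = "numeric",
    allo = "numeric",
    auto = "numeric",
    unassigned = "numeric",
    sampleID = "character"
  )
)

.validFRIResult <- function(object) {
  msg <- character()
  if (length(object@phi) != 5L) msg <- c(msg, "phi must have length 5")
  if (any(object@phi < -1e-9)) msg <- c(msg, "regional volumes must be >= 0")
  if (length(object@shares) != 5L) msg <- c(msg, "shares must have length 5")
  if (abs(object@allo + object@auto - object@phiTotal) >
      1e-8 * max(1, abs(object@phiTotal))) {
    msg <- c(msg, "allo + auto must equal phiTotal")
  }
  if (length(msg)) msg else TRUE
}
setValidity("FRIResult", .validFRIResult)

#' RiskParams: exposure parameters for drinking-water risk assessment
#'
#' USEPA-style exposure parameterisation for the dietary (drinking
#' water) route. Defaults follow the adult scenario commonly used for
#' surface-water phthalate screening: 2 L/day consumption, 60 kg body
#' weight, 350 exposure days per year over 30 years, averaged over
#' 26,280 days, with oral reference doses of 1.0 (DMP), 0.8 (DEP) and
#' 0.1 (DBP) mg kg^-1 day^-1. Cancer slope factors are optional; none
#' are configured by default because DMP, DEP and DBP are treated as
#' non-cancer compounds.
#'
#' @slot dr numeric, daily water consumption (L/day)
#' @slot ef numeric, exposure frequency (days/year)
#' @slot ed numeric, exposure duration (years)
#' @slot bw numeric, body weight (kg)
#' @slot at numeric, averaging time (days)
#' @slot rfd named numeric, reference doses (mg kg^-1 day^-1)
#' @slot csf named numeric, cancer slope factors ((mg kg^-1 day^-1)^-1),
#'   may be empty
#' @seealso [riskParams()], [assessRisk()]
#' @export
setClass("RiskParams",
  representation(
    dr = "numeric", ef = "numeric", ed = "numeric",
    bw = "numeric", at = "numeric",
    rfd = "numeric", csf = "numeric"
  )
)

.validRiskParams <- function(object) {
  msg <- character()
  for (nm in c("dr", "ef", "ed", "bw", "at")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      msg <- c(msg, sprintf("%s must be a single positive number", nm))
    }
  }
  if (length(object@rfd) == 0L || is.null(names(object@rfd)) ||
      any(!nzchar(names(object@rfd)))) {
    msg <- c(msg, "rfd must be a named numeric vector")
  }
  if (any(object@rfd <= 0)) msg <- c(msg, "reference doses must be positive")
  if (length(object@csf) && (is.null(names(object@csf)) ||
                             any(object@csf <= 0))) {
    msg <- c(msg, "csf must be a named positive numeric vector")
  }
  if (length(msg)) msg else TRUE
}
setValidity("RiskParams", .validRiskParams)

#' RiskResult: per-congener doses, quotients and indices
#'
#' @slot add named numeric, average daily dose per congener
#'   (mg kg^-1 day^-1)
#' @slot hq named numeric, hazard quotients (ADD/RfD)
#' @slot hi numeric scalar, hazard index (sum of HQs)
#' @slot classification character, "low non-cancer risk",
#'   "high non-cancer risk" or "boundary"
#' @slot cr named numeric, carcinogenic risks (empty if no slope factors)
#' @slot ri numeric, risk index (NA when not evaluated)
#' @slot tier character, carcinogenic tier or "not-evaluated"
#' @seealso [assessRisk()]
#' @export
setClass("RiskResult",
  representation(
    add = "numeric", hq = "numeric", hi = "numeric",
    classification = "character",
    cr = "numeric", ri = "numeric", tier = "character"
  )
)

.validRiskResult <- function(object) {
  msg <- character()
  if (any(object@hq < 0)) msg <- c(msg, "hazard quotients must be >= 0")
  if (abs(object@hi - sum(object@hq)) > 1e-12 * max(1, object@hi)) {
    msg <- c(msg, "hi must equal the sum of the hazard quotients")
  }
  if (length(msg)) msg else TRUE
}
setValidity("RiskResult", .validRiskResult)
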