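#' @include AllClasses.R
NULL

#' Napierian CDOM absorption coefficients
#'
#' Converts measured optical density to Napierian absorption
#' coefficients, \code{a(lambda) = 2.303 * OD(lambda) / gamma}, with
#' gamma the cuvette path length in metres (0.01 m for a 1 cm cell), so
#' a is in m^-1. An optional null-point offset (the mean coefficient
#' over a long-wavelength window where CDOM absorption is negligible)
#' can be subtracted; it is off by default.
#'
#' @param spec an [AbsorptionSpectrum-class]
#' @param nullWindow optional c(low, high) nm window for offset
#'   subtraction, e.g. c(700, 800); NULL (default) disables it
#' @return data.frame with columns \code{wavelength_nm} and
#'   \code{a_per_m}
#' @export
napierianAbsorption <- function(spec, nullWindow = NULL) {
  stopifnot(is(spec, "AbsorptionSpectrum"))
  a <- 2.303 * spec@opticalDensity / spec@pathLength
  if (!is.null(nullWindow)) {
    inWin <- spec@wavelength >= nullWindow[1L] &
      spec@wavelength <= nullWindow[2L]
    if (!any(inWin)) stop("null window contains no measured wavelengths")
    a <- a - mean(a[inWin])
  }
  data.frame(wavelength_nm = spec@wavelength, a_per_m = a)
}

# coefficient at a wavelength (exact grid match or linear interpolation)
.aAt <- function(a, lambda) {
  wl <- a$wavelength_nm
  if (lambda < min(wl) - 1e-6 || lambda > max(wl) + 1e-6) {
    stop(sprintf("wavelength %g nm outside the measured range %g-%g nm",
                 lambda, min(wl), max(wl)))
  }
  stats::approx(wl, a$a_per_m, xout = lambda, ties = "ordered")$y
}

#' CDOM spectral slope
#'
#' Exponential decay slope of the absorption spectrum over a wavelength
#' window (default 275-295 nm, the molecular-size tracer), estimated by
#' ordinary least squares on \code{ln a(lambda)} versus lambda within
#' the closed window. Positive S means decay with wavelength; units are
#' nm^-1. Non-positive coefficients inside the window are dropped; if
#' fewer than \code{minPoints} remain the slope is NA with a warning.
#'
#' @param a coefficient series from [napierianAbsorption()]
#' @param window closed wavelength window, default c(275, 295)
#' @param minPoints minimum usable points, default 5
#' @return slope S in nm^-1 (NA when not estimable)
#' @export
spectralSlope <- function(a, window = c(275, 295), minPoints = 5L) {
  inWin <- a$wavelength_nm >= window[1L] & a$wavelength_nm <= window[2L]
  wl <- a$wavelength_nm[inWin]
  av <- a$a_per_m[inWin]
  keep <- is.finite(av) & av > 0
  wl <- wl[keep]; av <- av[keep]
  if (length(wl) < minPoints) {
    warning(sprintf(
      "fewer than %d positive coefficients in %g-%g nm; slope is NA",
      minPoints, window[1L], window[2L]))
    return(NA_real_)
  }
  fit <- stats::lm.fit(cbind(1, wl), log(av))
  -unname(fit$coefficients[2L])
}

#' E250:365 absorption ratio
#'
#' The ratio a(250)/a(365); higher values indicate lower aromaticity and
#' smaller molecular weight of the CDOM pool.
#'
#' @param a coefficient series from [napierianAbsorption()]
#' @return unitless ratio
#' @export
eRatio <- function(a) {
  num <- .aAt(a, 250)
  den <- .aAt(a, 365)
  if (!is.finite(den) || den <= 0) stop("a(365) must be positive")
  num / den
}

#' SUVA254 aromaticity proxy
#'
#' SUVA254 = a(254) / DOC, in L mg C^-1 m^-1, using the Napierian
#' coefficient. Non-positive DOC yields NA.
#'
#' @param a254 Napierian absorption coefficient at 254 nm (m^-1)
#' @param doc dissolved organic carbon concentration (mg/L)
#' @return SUVA254 (NA when DOC <= 0)
#' @export
suva254 <- function(a254, doc) {
  if (is.na(doc) || doc <= 0) return(NA_real_)
  a254 / doc
}

#' Spectral slope ratio S_R
#'
#' Ratio of the short-wavelength slope S(275-295) to the long-wavelength
#' slope S(350-400). NA when either slope is missing or the denominator
#' slope is zero (flat spectrum).
#'
#' @param a coefficient series from [napierianAbsorption()]
#' @return unitless ratio (NA when degenerate)
#' @export
slopeRatio <- function(a) {
  s1 <- spectralSlope(a, c(275, 295))
  s2 <- spectralSlope(a, c(350, 400))
  if (is.na(s1) || is.na(s2) || abs(s2) < 1e-12) return(NA_real_)
  s1 / s2
}

#' Per-sample CDOM optical summary
#'
#' Convenience wrapper computing the full index set for one sample:
#' a(350), a(254), S275-295, E250:365, SUVA254, S_R, the two
#' fluorescence indices and the source labels.
#'
#' @param spec an [AbsorptionSpectrum-class]
#' @param doc DOC concentration (mg/L), for SUVA254
#' @param eem optional corrected [EEMGrid-class] for FI370/FI310
#' @return one-row data.frame
#' @export
cdomIndices <- function(spec, doc = NA_real_, eem = NULL) {
  a <- napierianAbsorption(spec)
  fi370 <- fi310 <- NA_real_
  if (!is.null(eem)) {
    fi370 <- suppressWarnings(fluorescenceIndex(eem, "FI370"))
    fi310 <- suppressWarnings(fluorescenceIndex(eem, "FI310"))
  }
  src <- classifySource(fi370, fi310)
  data.frame(
    sample_id = spec@sampleID,
    a350_per_m = .aAt(a, 350),
    a254_per_m = .aAt(a, 254),
    s275_295_per_nm = spectralSlope(a, c(275, 295)),
    e250_365 = eRatio(a),
    suva254 = suva254(.aAt(a, 254), doc),
    slope_ratio = slopeRatio(a),
    fi370 = fi370, fi310 = fi310,
    fulvic_source = src$fulvic,
    autochthonous_level = src$autochthonous,
    stringsAsFactors = FALSE
  )
}
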