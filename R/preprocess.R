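#' @include AllClasses.R
NULL

.sameAxes <- function(a, b) {
  length(a@excitation) == length(b@excitation) &&
    length(a@emission) == length(b@emission) &&
    all(abs(a@excitation - b@excitation) < 1e-6) &&
    all(abs(a@emission - b@emission) < 1e-6)
}

#' Blank subtraction
#'
#' Subtracts a Milli-Q water blank EEM from a sample EEM, element-wise.
#' Negative differences (noise exceeding the sample signal) are floored
#' at zero so that downstream regional volumes are never reduced by
#' negative noise; the number of floored cells is recorded in the
#' attribute \code{"flooredCells"} of the returned object.
#'
#' @param eem sample [EEMGrid-class]
#' @param blank blank [EEMGrid-class] on identical axes
#' @return corrected [EEMGrid-class] with \code{"blank"} appended to its
#'   applied corrections
#' @export
subtractBlank <- function(eem, blank) {
  stopifnot(is(eem, "EEMGrid"), is(blank, "EEMGrid"))
  if (!.sameAxes(eem, blank)) {
    stop("sample and blank EEMs must share identical wavelength axes")
  }
  I <- eem@intensity - blank@intensity
  floored <- sum(I < 0)
  I[I < 0] <- 0
  out <- EEMGrid(eem@excitation, eem@emission, I,
                 sampleID = eem@sampleID,
                 correctionsApplied = union(eem@correctionsApplied, "blank"),
                 mask = eem@mask)
  attr(out, "flooredCells") <- floored
  out
}

# Logical matrix of cells falling in the first- or second-order
# Rayleigh scatter bands. Membership is decided purely by the
# inequalities |em - ex| <= w1, |em - 2 ex| <= w2.
.scatterBands <- function(ex, em, w1, w2) {
  d1 <- abs(outer(ex, em, function(x, m) m - x))
  d2 <- abs(outer(ex, em, function(x, m) m - 2 * x))
  d1 <= w1 | d2 <= w2
}

#' Rayleigh scatter band excision
#'
#' Removes first-order (emission near excitation) and second-order
#' (emission near twice excitation) scatter ridges. A cell is excised
#' when |lambda_em - lambda_ex| <= \code{firstOrderHalfwidth} or
#' |lambda_em - 2 lambda_ex| <= \code{secondOrderHalfwidth}. With
#' \code{mode = "interpolate"} each excised cell is refilled by linear
#' interpolation along the emission axis between the nearest retained
#' neighbours; runs touching the start or end of the emission axis are
#' anchored to zero at the spectrum edge. With \code{mode = "zero"}
#' excised cells are set to 0 and flagged in the mask. Cells outside
#' both bands are untouched.
#'
#' @param eem an [EEMGrid-class]
#' @param firstOrderHalfwidth half-width of the first-order band (nm)
#' @param secondOrderHalfwidth half-width of the second-order band (nm)
#' @param mode "interpolate" (default) or "zero"
#' @return corrected [EEMGrid-class] with \code{"scatter"} appended
#' @export
removeScatter <- function(eem, firstOrderHalfwidth = 15,
                          secondOrderHalfwidth = 15,
                          mode = c("interpolate", "zero")) {
  stopifnot(is(eem, "EEMGrid"),
            firstOrderHalfwidth > 0, secondOrderHalfwidth > 0)
  mode <- match.arg(mode)
  ex <- eem@excitation
  em <- eem@emission
  I <- eem@intensity
  band <- .scatterBands(ex, em, firstOrderHalfwidth, secondOrderHalfwidth)
  mask <- eem@mask
  if (mode == "zero") {
    I[band] <- 0
    mask <- mask | band
  } else {
    for (i in seq_along(ex)) {
      cut <- band[i, ]
      if (!any(cut)) next
      if (all(cut)) {
        I[i, ] <- 0
        next
      }
      xs <- em[!cut]
      ys <- I[i, !cut]
      # zero anchors at the spectrum edges when the edge cell is excised
      if (cut[1L]) { xs <- c(em[1L], xs); ys <- c(0, ys) }
      n <- length(em)
      if (cut[n]) { xs <- c(xs, em[n]); ys <- c(ys, 0) }
      I[i, cut] <- stats::approx(xs, ys, xout = em[cut],
                                 method = "linear", ties = "ordered")$y
    }
  }
  EEMGrid(ex, em, I, sampleID = eem@sampleID,
          correctionsApplied = union(eem@correctionsApplied, "scatter"),
          mask = mask)
}

# Optical density at requested wavelengths; exact grid match within
# 1e-6 nm preferred, otherwise linear interpolation inside coverage.
.odAt <- function(spec, lambda) {
  wl <- spec@wavelength
  if (any(lambda < min(wl) - 1e-6) || any(lambda > max(wl) + 1e-6)) {
    stop(sprintf(
      "absorbance spectrum (%g-%g nm) does not cover requested %g-%g nm",
      min(wl), max(wl), min(lambda), max(lambda)))
  }
  stats::approx(wl, spec@opticalDensity, xout = lambda,
                method = "linear", ties = "ordered", rule = 1)$y
}

#' Inner-filter effect correction
#'
#' Standard absorbance-based correction: each cell is multiplied by
#' \code{10^((A(lambda_ex) + A(lambda_em)) / 2)} where A is the decadic
#' optical density measured in the same 1 cm cell geometry as the
#' fluorescence acquisition. The absorbance spectrum must cover every
#' excitation and emission wavelength of the EEM; there is no
#' extrapolation.
#'
#' @param eem an [EEMGrid-class]
#' @param spec an [AbsorptionSpectrum-class] covering the EEM axes
#' @return corrected [EEMGrid-class] with \code{"inner_filter"} appended
#' @export
innerFilterCorrect <- function(eem, spec) {
  stopifnot(is(eem, "EEMGrid"), is(spec, "AbsorptionSpectrum"))
  aex <- .odAt(spec, eem@excitation)
  aem <- .odAt(spec, eem@emission)
  factor <- 10^(outer(aex, aem, "+") / 2)
  EEMGrid(eem@excitation, eem@emission, eem@intensity * factor,
          sampleID = eem@sampleID,
          correctionsApplied = union(eem@correctionsApplied,
                                     "inner_filter"),
          mask = eem@mask)
}
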