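#' @include AllClasses.R
NULL

#' Default five-region FRI scheme
#'
#' The conventional five-region partition of the EEM plane used for
#' fluorescence regional integration: tyrosine-like (R1, Ex 200-250 /
#' Em 280-330 nm), tryptophan-like (R2, Ex 200-250 / Em 330-380),
#' fulvic-like (R3, Ex 200-250 / Em 380-550), microbial protein-like
#' (R4, Ex 250-400 / Em 280-380) and humic-like (R5, Ex 250-400 /
#' Em 380-550). Boundaries are half-open, \code{[low, high)}, on both
#' axes, which resolves the shared 250/330/380 nm edges so the regions
#' form a true partition and the shares sum to one. Regions are clipped
#' to the measured grid during integration (the usual acquisition
#' starts at excitation 220 nm although R1-R3 nominally start at 200).
#'
#' @return data.frame with columns \code{region}, \code{ex_low},
#'   \code{ex_high}, \code{em_low}, \code{em_high}, \code{label}
#' @export
defaultRegions <- function() {
  data.frame(
    region = 1:5,
    ex_low = c(200, 200, 200, 250, 250),
    ex_high = c(250, 250, 250, 400, 400),
    em_low = c(280, 330, 380, 280, 380),
    em_high = c(330, 380, 550, 380, 550),
    label = c("tyrosine-like", "tryptophan-like", "fulvic-like",
              "microbial protein-like", "humic-like"),
    stringsAsFactors = FALSE
  )
}

#' Read / write a region table as YAML
#'
#' The region scheme can be overridden from a YAML file holding a list
#' of records with keys \code{region, ex_low, ex_high, em_low, em_high,
#' label}.
#'
#' @param path YAML file
#' @param regions region table as from [defaultRegions()]
#' @return for \code{readRegions}, a region data.frame
#' @export
readRegions <- function(path) {
  recs <- yaml::read_yaml(path)
  df <- do.call(rbind, lapply(recs, function(r) {
    data.frame(region = as.integer(r$region),
               ex_low = as.numeric(r$ex_low),
               ex_high = as.numeric(r$ex_high),
               em_low = as.numeric(r$em_low),
               em_high = as.numeric(r$em_high),
               label = as.character(r$label),
               stringsAsFactors = FALSE)
  }))
  .checkRegions(df)
  df
}

#' @rdname readRegions
#' @export
writeRegions <- function(regions, path) {
  .checkRegions(regions)
  yaml::write_yaml(lapply(seq_len(nrow(regions)), function(i)
    as.list(regions[i, ])), path)
  invisible(path)
}

.checkRegions <- function(regions) {
  need <- c("region", "ex_low", "ex_high", "em_low", "em_high")
  miss <- setdiff(need, names(regions))
  if (length(miss)) stop("region table lacks: ", paste(miss, collapse = ", "))
  if (any(regions$ex_high <= regions$ex_low) ||
      any(regions$em_high <= regions$em_low)) {
    stop("region bounds must satisfy low < high")
  }
  invisible(regions)
}

# Regular grid step; errors on irregular spacing.
.gridStep <- function(axis, what) {
  if (length(axis) < 2L) stop("axis too short to infer spacing")
  d <- diff(axis)
  if (max(d) - min(d) > 1e-6) {
    stop(what, " axis is irregular; resample the EEM onto a regular ",
         "grid before integration")
  }
  mean(d)
}

.requireCorrected <- function(eem, force) {
  if (force) return(invisible(NULL))
  need <- c("blank", "scatter")
  miss <- setdiff(need, eem@correctionsApplied)
  if (length(miss)) {
    stop("EEM lacks corrections: ", paste(miss, collapse = ", "),
         ". Apply subtractBlank()/removeScatter() or set force = TRUE.")
  }
  invisible(NULL)
}

#' Integrate the EEM over one region
#'
#' Riemann sum of fluorescence intensity over the grid points inside a
#' region: \code{sum(I * d_ex * d_em)} where the wavelength steps are
#' inferred from the (regular) axes — 5 nm excitation and 1 nm emission
#' on the default grid. A grid point belongs to the region iff
#' \code{low <= lambda < high} on both axes; the part of a region lying
#' outside the measured axes contributes nothing.
#'
#' @param eem an [EEMGrid-class] (corrected, unless \code{force})
#' @param region one-row region definition (as a row of
#'   [defaultRegions()] or a list with the same fields)
#' @param force skip the blank/scatter correction check
#' @return volume in intensity x nm^2
#' @export
integrateRegion <- function(eem, region, force = FALSE) {
  stopifnot(is(eem, "EEMGrid"))
  .requireCorrected(eem, force)
  dex <- .gridStep(eem@excitation, "excitation")
  dem <- .gridStep(eem@emission, "emission")
  inEx <- eem@excitation >= region$ex_low & eem@excitation < region$ex_high
  inEm <- eem@emission >= region$em_low & eem@emission < region$em_high
  if (!any(inEx) || !any(inEm)) return(0)
  sum(eem@intensity[inEx, inEm, drop = FALSE]) * dex * dem
}

#' Fluorescence regional integration
#'
#' Computes the five regional volumes Phi_i, the total Phi_T, the shares
#' P_i = Phi_i / Phi_T, the allochthonous sum (fulvic-like + humic-like,
#' R3 + R5) and the autochthonous sum (R1 + R2 + R4), plus the volume
#' over grid cells assigned to no region (reported for transparency of
#' the partition; on the default grid these are emission 550-600 nm and
#' excitation at or above 400 nm). No area-normalisation multiplication
#' factors are applied by default: the volumes are raw Riemann sums.
#' Setting \code{multiplicationFactors = TRUE} rescales each Phi_i by
#' the inverse of its region's fractional grid area, the classical
#' normalisation for unequal region sizes.
#'
#' @param eem an [EEMGrid-class]
#' @param regions region table; default [defaultRegions()]
#' @param force skip the correction check
#' @param multiplicationFactors apply area-normalisation factors
#' @return an [FRIResult-class]
#' @export
friComponents <- function(eem, regions = defaultRegions(), force = FALSE,
                          multiplicationFactors = FALSE) {
  stopifnot(is(eem, "EEMGrid"))
  .checkRegions(regions)
  if (nrow(regions) != 5L) stop("exactly five regions are expected")
  .requireCorrected(eem, force)
  dex <- .gridStep(eem@excitation, "excitation")
  dem <- .gridStep(eem@emission, "emission")
  phis <- numeric(5)
  cellCounts <- numeric(5)
  assigned <- matrix(FALSE, length(eem@excitation), length(eem@emission))
  for (i in seq_len(5)) {
    r <- regions[i, ]
    inEx <- eem@excitation >= r$ex_low & eem@excitation < r$ex_high
    inEm <- eem@emission >= r$em_low & eem@emission < r$em_high
    if (any(assigned[inEx, inEm])) stop("regions overlap on the grid")
    assigned[inEx, inEm] <- TRUE
    phis[i] <- sum(eem@intensity[inEx, inEm, drop = FALSE]) * dex * dem
    cellCounts[i] <- sum(inEx) * sum(inEm)
  }
  if (multiplicationFactors) {
    totalCells <- length(assigned)
    mf <- ifelse(cellCounts > 0, totalCells / cellCounts / 5, 0)
    phis <- phis * mf
  }
  names(phis) <- paste0("phi", 1:5)
  phiT <- sum(phis)
  unassigned <- sum(eem@intensity[!assigned]) * dex * dem
  if (phiT > 0) {
    shares <- phis / phiT
  } else {
    warning("total FRI volume is zero; shares are undefined")
    shares <- rep(NA_real_, 5)
  }
  names(shares) <- paste0("p", 1:5)
  new("FRIResult", phi = phis, phiTotal = phiT, shares = shares,
      allo = phis[[3L]] + phis[[5L]],
      auto = phis[[1L]] + phis[[2L]] + phis[[4L]],
      unassigned = unassigned, sampleID = eem@sampleID)
}

.gridIndex <- function(axis, lambda, what) {
  i <- which(abs(axis - lambda) < 1e-6)
  if (length(i) != 1L) {
    stop(sprintf("%s wavelength %g nm is not on the measured grid",
                 what, lambda))
  }
  i
}

.emissionRatio <- function(eem, exNm, emNumNm, emDenNm, name) {
  i <- .gridIndex(eem@excitation, exNm, "excitation")
  jn <- .gridIndex(eem@emission, emNumNm, "emission")
  jd <- .gridIndex(eem@emission, emDenNm, "emission")
  if (eem@mask[i, jn] || eem@mask[i, jd]) {
    stop(name, " cells were excised by scatter removal; rerun ",
         "removeScatter() with mode = 'interpolate'")
  }
  den <- eem@intensity[i, jd]
  if (den <= 0) {
    warning(name, " denominator intensity is <= 0; returning NA")
    return(NA_real_)
  }
  eem@intensity[i, jn] / den
}

#' Fluorescence source indices FI370 and FI310
#'
#' FI370 is the emission-intensity ratio I(370, 450) / I(370, 500),
#' separating terrestrially derived (< 1.4) from microbially derived
#' (> 1.9) fulvic material. FI310 is I(310, 380) / I(310, 430), indexing
#' the autochthonous contribution (< 0.7 low, 0.7-0.8 intermediate,
#' > 0.8 high).
#'
#' @param eem an [EEMGrid-class]; the four required cells must be on the
#'   grid and not excised
#' @param which \code{"FI370"} or \code{"FI310"}
#' @return the index value (NA with a warning when the denominator
#'   intensity is not positive)
#' @seealso [classifySource()]
#' @export
fluorescenceIndex <- function(eem, which = c("FI370", "FI310")) {
  stopifnot(is(eem, "EEMGrid"))
  which <- match.arg(which)
  if (which == "FI370") {
    .emissionRatio(eem, 370, 450, 500, "FI370")
  } else {
    .emissionRatio(eem, 310, 380, 430, "FI310")
  }
}

#' Classify CDOM source from the fluorescence indices
#'
#' FI370 below 1.4 indicates terrestrially derived material, above 1.9
#' microbially derived, in between intermediate. FI310 below 0.7
#' indicates low autochthonous contribution, 0.7-0.8 (inclusive)
#' intermediate, above 0.8 high.
#'
#' @param fi370,fi310 index values
#' @return list with elements \code{fulvic} and \code{autochthonous}
#'   (character labels; NA input gives NA label)
#' @export
classifySource <- function(fi370, fi310) {
  fulvic <- if (is.na(fi370)) NA_character_
            else if (fi370 < 1.4) "terrestrial"
            else if (fi370 > 1.9) "microbial"
            else "intermediate"
  auto <- if (is.na(fi310)) NA_character_
          else if (fi310 < 0.7) "autochthonous-low"
          else if (fi310 > 0.8) "autochthonous-high"
          else "autochthonous-intermediate"
  list(fulvic = fulvic, autochthonous = auto)
}
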