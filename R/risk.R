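#' @include AllClasses.R
NULL

#' Exposure parameters for the drinking-water route
#'
#' Builds a validated [RiskParams-class]. Defaults are the adult
#' drinking-water scenario: DR 2 L/day, EF 350 days/year, ED 30 years,
#' BW 60 kg, AT 26,280 days, with oral reference doses DMP 1.0, DEP 0.8,
#' DBP 0.1 mg kg^-1 day^-1 (i.e. 1000/800/100 ug kg^-1 day^-1 converted
#' once here; concentrations are mg/L throughout the package). AT is
#' used exactly as configured; \code{strictAveragingTime = TRUE}
#' recomputes AT = ED * 365 for sensitivity analysis.
#'
#' @param dr daily water consumption (L/day)
#' @param ef exposure frequency (days/year)
#' @param ed exposure duration (years)
#' @param bw body weight (kg)
#' @param at averaging time (days)
#' @param rfd named reference doses (mg kg^-1 day^-1)
#' @param csf named cancer slope factors ((mg kg^-1 day^-1)^-1); empty
#'   by default — DMP/DEP/DBP are treated as non-cancer compounds
#' @param strictAveragingTime recompute AT as ED * 365
#' @return a [RiskParams-class]
#' @export
riskParams <- function(dr = 2, ef = 350, ed = 30, bw = 60, at = 26280,
                       rfd = c(DMP = 1.0, DEP = 0.8, DBP = 0.1),
                       csf = numeric(), strictAveragingTime = FALSE) {
  if (strictAveragingTime) at <- ed * 365
  new("RiskParams", dr = dr, ef = ef, ed = ed, bw = bw, at = at,
      rfd = rfd, csf = csf)
}

#' Average daily dose
#'
#' ADD = (C * DR * EF * ED) / (BW * AT), in mg kg^-1 day^-1, for a water
#' concentration C in mg/L.
#'
#' @param conc concentration(s) in mg/L
#' @param params a [RiskParams-class]
#' @return ADD, same shape as \code{conc}
#' @export
averageDailyDose <- function(conc, params = riskParams()) {
  stopifnot(is(params, "RiskParams"))
  conc * params@dr * params@ef * params@ed / (params@bw * params@at)
}

#' Hazard quotient
#'
#' HQ = ADD / RfD. \code{rfd} can be given directly or looked up by
#' congener name in \code{params}.
#'
#' @param add average daily dose (mg kg^-1 day^-1)
#' @param rfd reference dose, or NULL to look up by \code{congener}
#' @param congener congener name for the lookup
#' @param params a [RiskParams-class]
#' @return hazard quotient
#' @export
hazardQuotient <- function(add, rfd = NULL, congener = NULL,
                           params = riskParams()) {
  if (is.null(rfd)) {
    if (is.null(congener)) stop("give either rfd or congener")
    if (!congener %in% names(params@rfd)) {
      stop("no reference dose configured for congener '", congener, "'")
    }
    rfd <- params@rfd[[congener]]
  }
  if (any(rfd <= 0)) stop("reference dose must be positive")
  add / rfd
}

#' Hazard index
#'
#' HI = sum of the hazard quotients across congeners. HI below 1 is
#' classified as low non-cancer risk, above 1 as high; exactly 1 is
#' labelled boundary.
#'
#' @param hqs numeric vector of hazard quotients (at least one)
#' @return list with \code{hi} and \code{classification}
#' @export
hazardIndex <- function(hqs) {
  hqs <- hqs[!is.na(hqs)]
  if (length(hqs) == 0L) stop("no hazard quotients to sum")
  hi <- sum(hqs)
  cls <- if (hi < 1) "low non-cancer risk"
         else if (hi > 1) "high non-cancer risk"
         else "boundary"
  list(hi = hi, classification = cls)
}

#' Carcinogenic risk and risk index
#'
#' CR = ADD * CSF per congener; RI = sum of CRs, tiered as very low
#' (< 1e-6), unacceptable (> 1e-4) or intermediate.
#'
#' @param add average daily dose
#' @param csf cancer slope factor
#' @return carcinogenic risk
#' @export
carcinogenicRisk <- function(add, csf) {
  if (any(csf <= 0)) stop("cancer slope factor must be positive")
  add * csf
}

#' @rdname carcinogenicRisk
#' @param crs numeric vector of carcinogenic risks
#' @return for \code{riskIndex}, a list with \code{ri} and \code{tier}
#' @export
riskIndex <- function(crs) {
  ri <- sum(crs)
  tier <- if (ri < 1e-6) "very low"
          else if (ri > 1e-4) "unacceptable"
          else "intermediate"
  list(ri = ri, tier = tier)
}

#' Full risk assessment for one exposure point
#'
#' Applies the dose, quotient and index chain to a named vector of
#' congener concentrations. Carcinogenic outputs are computed only for
#' congeners with a configured slope factor; with none configured (the
#' default — DMP, DEP and DBP are non-cancer compounds) the carcinogenic
#' branch is marked not-evaluated.
#'
#' @param conc named concentrations in mg/L, e.g.
#'   \code{c(DMP = 0.013, DEP = 0.299, DBP = 0.006)}
#' @param params a [RiskParams-class]
#' @return a [RiskResult-class]
#' @export
assessRisk <- function(conc, params = riskParams()) {
  stopifnot(is(params, "RiskParams"))
  if (is.null(names(conc)) || any(!nzchar(names(conc)))) {
    stop("concentrations must be a named vector of congeners")
  }
  missRfd <- setdiff(names(conc), names(params@rfd))
  if (length(missRfd)) {
    stop("no reference dose configured for congener(s): ",
         paste(missRfd, collapse = ", "))
  }
  add <- averageDailyDose(conc, params)
  hq <- mapply(function(a, nm) hazardQuotient(a, rfd = params@rfd[[nm]]),
               add, names(conc))
  names(add) <- names(hq) <- names(conc)
  hix <- hazardIndex(hq)
  withCsf <- intersect(names(conc), names(params@csf))
  if (length(withCsf)) {
    cr <- carcinogenicRisk(add[withCsf], params@csf[withCsf])
    rix <- riskIndex(cr)
    ri <- rix$ri; tier <- rix$tier
  } else {
    cr <- numeric(); ri <- NA_real_; tier <- "not-evaluated"
  }
  new("RiskResult", add = add, hq = hq, hi = hix$hi,
      classification = hix$classification, cr = cr, ri = ri, tier = tier)
}

#' Per-site risk table
#'
#' Runs [assessRisk()] on every row of a survey sample table and returns
#' a per-site data.frame of doses, quotients, HI and classification.
#'
#' @param samples sample table with \code{dmp_mg_per_l},
#'   \code{dep_mg_per_l}, \code{dbp_mg_per_l}
#' @param params a [RiskParams-class]
#' @return data.frame, one row per sample
#' @export
riskTable <- function(samples, params = riskParams()) {
  validateSamples(samples)
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    conc <- c(DMP = samples$dmp_mg_per_l[i],
              DEP = samples$dep_mg_per_l[i],
              DBP = samples$dbp_mg_per_l[i])
    res <- assessRisk(conc, params)
    data.frame(site_id = samples$site_id[i], season = samples$season[i],
               add_dmp = res@add[["DMP"]], add_dep = res@add[["DEP"]],
               add_dbp = res@add[["DBP"]],
               hq_dmp = res@hq[["DMP"]], hq_dep = res@hq[["DEP"]],
               hq_dbp = res@hq[["DBP"]],
               hi = res@hi, classification = res@classification,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percentage shares of congener concentrations
#'
#' Shares of the summed concentration, in percent. Used for the
#' composition table of a congener family.
#'
#' @param means named mean concentrations (mg/L)
#' @return named percentages summing to 100
#' @export
paeShares <- function(means) {
  tot <- sum(means)
  if (tot <= 0) stop("total concentration must be positive")
  100 * means / tot
}

#' PAE composition statistics
#'
#' Per-congener mean, median and maximum concentrations and percentage
#' shares of the summed-congener total, by season or overall. Overall
#' means are sample-size-weighted across seasons (equivalently, plain
#' means over the pooled samples).
#'
#' @param samples sample table with the three PAE columns
#' @param grouping \code{"season"} or \code{"overall"}
#' @return data.frame with one row per congener (plus a \code{sum3paes}
#'   attribute per group giving the summed mean)
#' @export
paeComposition <- function(samples, grouping = c("season", "overall")) {
  validateSamples(samples)
  grouping <- match.arg(grouping)
  cols <- c(DMP = "dmp_mg_per_l", DEP = "dep_mg_per_l",
            DBP = "dbp_mg_per_l")
  groups <- if (grouping == "season") split(samples, samples$season)
            else list(overall = samples)
  out <- lapply(names(groups), function(g) {
    df <- groups[[g]]
    if (nrow(df) == 0L) stop("empty group: ", g)
    means <- vapply(cols, function(cl) mean(df[[cl]], na.rm = TRUE), 1)
    names(means) <- names(cols)
    shares <- paeShares(means)
    data.frame(group = g, congener = names(cols), n = nrow(df),
               mean_mg_per_l = unname(means),
               median_mg_per_l = vapply(cols, function(cl)
                 stats::median(df[[cl]], na.rm = TRUE), 1),
               max_mg_per_l = vapply(cols, function(cl)
                 max(df[[cl]], na.rm = TRUE), 1),
               share_pct = unname(shares),
               sum3paes_mg_per_l = sum(means),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}
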