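#' @include AllClasses.R
NULL

# run code under a temporary RNG state when a seed is supplied
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Synthetic two-season survey configuration
#'
#' Defines the generative model for a synthetic lake survey: 25 June and
#' 20 October samples. Each sample carries two correlated lognormal
#' latent factors — terrestrial input T (higher in October) and
#' autochthonous production A (higher in June). Five Gaussian
#' fluorophores (one per FRI region) have amplitudes loading on the
#' latents: fulvic-like (R3) and humic-like (R5) on T, tyrosine-like
#' (R1) and tryptophan-like (R2) on A, microbial protein-like (R4) on a
#' T/A blend; each with its own lognormal amplitude jitter so that the
#' observed FRI-PAE correlations decay in the order R3 >= R4 > R5. CDOM
#' absorption is exponential with a(350) proportional to T and a
#' season-specific slope. DEP is linked to the latent T (not to the
#' fluorescence itself), so the observed fulvic-volume-DEP correlation
#' is an emergent, pipeline-mediated property; its noise sd is solved in
#' closed form from lognormal moments so that the population r^2 between
#' the fulvic-like amplitude and DEP equals \code{r2Target}. The
#' humic-like emission-peak centre is solved per season from the FI370
#' targets. Fluorescence magnitudes are instrument-unit arbitrary.
#'
#' @param nJun,nOct samples per campaign
#' @param excitation,emission acquisition grid (nm)
#' @param meanlogT,sdlogT,meanlogA,sdlogA,rhoTA latent distributions
#'   (named per season where applicable) and log-scale correlation
#' @param baseAmplitude per-region amplitude scale (instrument units)
#' @param amplitudeJitterSd per-region lognormal jitter sd
#' @param exCenter,exSigma,emCenter,emSigma Gaussian peak geometry (nm);
#'   the R5 emission centre entries are overwritten per season from
#'   \code{fi370Target}
#' @param r4Mix exponent of T in the R4 blend T^mix * A^(1-mix)
#' @param noiseSd additive EEM noise sd (instrument units)
#' @param ridgeAmplitude,ridgeSigma first/second-order Rayleigh ridge
#'   amplitudes and width (nm); the second-order amplitude is scaled by
#'   \code{ridge2Fraction}
#' @param ridge2Fraction second-order ridge relative amplitude
#' @param a350PerT a(350) in m^-1 per unit T
#' @param slopeS per-season CDOM spectral slope (nm^-1)
#' @param odNoise multiplicative absorbance noise sd
#' @param betaDEP DEP loading on T (mg/L per unit T)
#' @param r2Target target population r^2 between the fulvic-like
#'   amplitude and DEP
#' @param dmpPerA per-season DMP loading on A (mg/L per unit A)
#' @param dbpMean DBP lognormal median (mg/L)
#' @param fi370Target per-season FI370 calibration targets
#' @param docMean,docSd,chlaPerA per-season water-quality parameters
#' @return list of class \code{"cohortConfig"} including the derived
#'   \code{sigmaEps} (DEP noise sd) and seasonal R5 emission centres
#' @export
cohortConfig <- function(nJun = 25, nOct = 20,
                         excitation = seq(220, 450, by = 5),
                         emission = seq(250, 600, by = 1),
                         meanlogT = c(JUN = 0, OCT = log(1.5)),
                         sdlogT = 0.35,
                         meanlogA = c(JUN = log(1.2), OCT = log(0.8)),
                         sdlogA = 0.30,
                         rhoTA = 0.6,
                         baseAmplitude = c(R1 = 150, R2 = 150, R3 = 400,
                                           R4 = 250, R5 = 600),
                         amplitudeJitterSd = c(R1 = 0.2, R2 = 0.2,
                                               R3 = 0.05, R4 = 0.1,
                                               R5 = 0.4),
                         exCenter = c(R1 = 235, R2 = 235, R3 = 235,
                                      R4 = 325, R5 = 325),
                         exSigma = c(R1 = 7, R2 = 7, R3 = 7,
                                     R4 = 35, R5 = 30),
                         emCenter = c(R1 = 305, R2 = 355, R3 = 465,
                                      R4 = 330, R5 = NA),
                         emSigma = c(R1 = 11, R2 = 11, R3 = 38,
                                     R4 = 22, R5 = 40),
                         r4Mix = 0.7,
                         noiseSd = 1.0,
                         ridgeAmplitude = 300, ridgeSigma = 4,
                         ridge2Fraction = 0.2,
                         a350PerT = 2.1,
                         slopeS = c(JUN = 0.020, OCT = 0.018),
                         odNoise = 0.005,
                         betaDEP = 0.28,
                         r2Target = 0.78,
                         dmpPerA = c(JUN = 0.0108, OCT = 0.0075),
                         dbpMean = 0.006,
                         fi370Target = c(JUN = 1.39, OCT = 1.14),
                         docMean = c(JUN = 26.38, OCT = 23.63),
                         docSd = c(JUN = 2.09, OCT = 1.62),
                         chlaPerA = c(JUN = 32, OCT = 18)) {
  stopifnot(nJun >= 1, nOct >= 1, r2Target > 0, r2Target < 1,
            all(baseAmplitude >= 0), noiseSd >= 0)
  cfg <- as.list(environment())
  # FI370 = g5(450)/g5(500) = exp(25 * (950 - 2*c) / sigma^2) at the R5
  # emission peak; invert for the per-season peak centre c.
  s2 <- emSigma[["R5"]]^2
  cfg$emCenterR5 <- (950 - s2 * log(fi370Target) / 25) / 2
  # Closed-form calibration of the DEP noise sd: with X = T*exp(eta3)
  # (the fulvic-like amplitude up to scale) and Y = beta*T + eps,
  # r^2(X, Y) = beta^2 cov(X,T)^2 / (VarX * (beta^2 VarT + sigma^2)).
  # Pooled lognormal moments over the two seasons give cov and Var.
  w <- c(nJun, nOct) / (nJun + nOct)
  mu <- meanlogT[c("JUN", "OCT")]
  ET <- sum(w * exp(mu + sdlogT^2 / 2))
  ET2 <- sum(w * exp(2 * mu + 2 * sdlogT^2))
  varT <- ET2 - ET^2
  s3 <- amplitudeJitterSd[["R3"]]
  k <- exp(s3^2 / 2)
  covXT <- k * varT
  varX <- ET2 * exp(2 * s3^2) - ET^2 * exp(s3^2)
  sig2 <- betaDEP^2 * (covXT^2 / (varX * r2Target) - varT)
  if (sig2 <= 0) {
    stop("r2Target is unattainable given the amplitude jitter")
  }
  cfg$sigmaEps <- sqrt(sig2)
  class(cfg) <- "cohortConfig"
  cfg
}

.gauss <- function(x, center, sigma) exp(-((x - center) / sigma)^2 / 2)

# per-fluorophore peak table for one season
.peakTable <- function(config, season) {
  emC <- config$emCenter
  emC[["R5"]] <- config$emCenterR5[[season]]
  data.frame(fluor = names(config$baseAmplitude),
             exC = unname(config$exCenter), exS = unname(config$exSigma),
             emC = unname(emC), emS = unname(config$emSigma))
}

# deterministic Rayleigh ridge pattern on the grid (shared by sample
# and blank, so blank subtraction removes it up to noise)
.ridge <- function(ex, em, config) {
  if (config$ridgeAmplitude <= 0) {
    return(matrix(0, length(ex), length(em)))
  }
  d1 <- outer(ex, em, function(x, m) m - x)
  d2 <- outer(ex, em, function(x, m) m - 2 * x)
  config$ridgeAmplitude * (.gauss(d1, 0, config$ridgeSigma) +
    config$ridge2Fraction * .gauss(d2, 0, config$ridgeSigma))
}

#' Generate one synthetic EEM
#'
#' Sum of five 2-D Gaussian fluorophores on the acquisition grid, plus
#' deterministic Rayleigh ridges, optional inner-filter attenuation by a
#' sample absorbance spectrum, and additive Gaussian noise. The analytic
#' truncated mass of each fluorophore inside each FRI region (the ground
#' truth the pipeline should recover) is attached as attribute
#' \code{"truth"}, a 5 x 5 fluorophore-by-region matrix.
#'
#' @param amplitudes named numeric, one amplitude per fluorophore
#'   R1..R5 (instrument units)
#' @param config a [cohortConfig()]
#' @param season "JUN" or "OCT" (selects the humic-like peak centre)
#' @param seed optional seed (RNG state is restored afterwards)
#' @param spectrum optional [AbsorptionSpectrum-class]; when given the
#'   EEM is attenuated by 10^-((A_ex + A_em)/2), the inner-filter effect
#'   the preprocessing stage undoes
#' @param ridge include the Rayleigh ridges
#' @param noise include additive noise
#' @param sampleID sample identifier
#' @return an [EEMGrid-class] with attribute \code{"truth"}
#' @export
generateEEM <- function(amplitudes, config = cohortConfig(),
                        season = "JUN", seed = NULL, spectrum = NULL,
                        ridge = TRUE, noise = TRUE, sampleID = "synthetic") {
  stopifnot(all(names(config$baseAmplitude) %in% names(amplitudes)))
  .withSeed(seed, {
    ex <- config$excitation
    em <- config$emission
    peaks <- .peakTable(config, season)
    I <- matrix(0, length(ex), length(em))
    for (i in seq_len(nrow(peaks))) {
      p <- peaks[i, ]
      I <- I + amplitudes[[p$fluor]] *
        outer(.gauss(ex, p$exC, p$exS), .gauss(em, p$emC, p$emS))
    }
    if (ridge) I <- I + .ridge(ex, em, config)
    if (!is.null(spectrum)) {
      aex <- .odAt(spectrum, ex)
      aem <- .odAt(spectrum, em)
      I <- I * 10^(-outer(aex, aem, "+") / 2)
    }
    if (noise && config$noiseSd > 0) {
      I <- I + matrix(stats::rnorm(length(I), sd = config$noiseSd),
                      nrow(I))
    }
    out <- EEMGrid(ex, em, I, sampleID = sampleID)
    attr(out, "truth") <- regionMassTruth(amplitudes, config, season)
    out
  })
}

#' Analytic fluorophore mass per FRI region
#'
#' Truncated-Gaussian mass of each fluorophore inside each region,
#' clipped to the measured grid coverage: amplitude * 2 pi sx sy *
#' (normal probability over the clipped excitation range) * (ditto
#' emission). This is the ground truth against which Riemann-sum FRI
#' volumes are checked.
#'
#' @inheritParams generateEEM
#' @param regions region table, default [defaultRegions()]
#' @return 5 x 5 matrix, fluorophores in rows, regions in columns
#' @export
regionMassTruth <- function(amplitudes, config = cohortConfig(),
                            season = "JUN", regions = defaultRegions()) {
  ex <- config$excitation
  em <- config$emission
  dex <- ex[2L] - ex[1L]
  dem <- em[2L] - em[1L]
  covEx <- c(min(ex), max(ex) + dex)
  covEm <- c(min(em), max(em) + dem)
  peaks <- .peakTable(config, season)
  m <- matrix(0, nrow(peaks), nrow(regions),
              dimnames = list(peaks$fluor,
                              paste0("R", regions$region)))
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    for (r in seq_len(nrow(regions))) {
      xlo <- max(regions$ex_low[r], covEx[1L])
      xhi <- min(regions$ex_high[r], covEx[2L])
      ylo <- max(regions$em_low[r], covEm[1L])
      yhi <- min(regions$em_high[r], covEm[2L])
      if (xlo >= xhi || ylo >= yhi) next
      px <- stats::pnorm(xhi, p$exC, p$exS) - stats::pnorm(xlo, p$exC, p$exS)
      py <- stats::pnorm(yhi, p$emC, p$emS) - stats::pnorm(ylo, p$emC, p$emS)
      m[i, r] <- amplitudes[[p$fluor]] * 2 * pi * p$exS * p$emS * px * py
    }
  }
  m
}

# bivariate lognormal latent draw
.drawLatents <- function(n, season, config) {
  zT <- stats::rnorm(n)
  zA <- config$rhoTA * zT + sqrt(1 - config$rhoTA^2) * stats::rnorm(n)
  list(T = exp(config$meanlogT[[season]] + config$sdlogT * zT),
       A = exp(config$meanlogA[[season]] + config$sdlogA * zA))
}

#' Generate a full synthetic survey
#'
#' Draws the two-season cohort: per-sample latents, fluorophore
#' amplitudes, EEMs (with ridges, inner-filter attenuation and noise), a
#' shared blank EEM, exponential absorbance spectra, water-quality
#' covariates and PAE concentrations. Everything derives from the single
#' seed, so identical seed and configuration reproduce the bundle
#' exactly.
#'
#' @param config a [cohortConfig()]
#' @param seed integer seed
#' @return list of class \code{"cohortBundle"}: \code{samples}
#'   (data.frame), \code{eems} (list of [EEMGrid-class]), \code{blank},
#'   \code{spectra} (list of [AbsorptionSpectrum-class]) and
#'   \code{truth} (latents, true slopes, true regional masses, the DEP
#'   loading and calibrated noise sd)
#' @export
generateCohort <- function(config = cohortConfig(), seed = 1) {
  .withSeed(seed, {
    ex <- config$excitation
    em <- config$emission
    plan <- data.frame(
      site_id = c(seq_len(config$nJun), seq_len(config$nOct)),
      season = rep(c("JUN", "OCT"), c(config$nJun, config$nOct)),
      stringsAsFactors = FALSE)
    n <- nrow(plan)
    eems <- vector("list", n)
    spectra <- vector("list", n)
    truthMass <- vector("list", n)
    lat <- data.frame(T = numeric(n), A = numeric(n), S = numeric(n))
    samp <- plan
    for (col in .SAMPLE_NUMERIC) samp[[col]] <- NA_real_
    for (s in c("JUN", "OCT")) {
      idx <- which(plan$season == s)
      d <- .drawLatents(length(idx), s, config)
      lat$T[idx] <- d$T
      lat$A[idx] <- d$A
      lat$S[idx] <- config$slopeS[[s]]
    }
    jit <- config$amplitudeJitterSd
    for (i in seq_len(n)) {
      s <- plan$season[i]
      Tv <- lat$T[i]; Av <- lat$A[i]
      drive <- c(R1 = Av, R2 = Av, R3 = Tv,
                 R4 = Tv^config$r4Mix * Av^(1 - config$r4Mix), R5 = Tv)
      amps <- config$baseAmplitude * drive *
        exp(stats::rnorm(5, sd = jit[names(drive)]))
      id <- sprintf("site%02d_%s", plan$site_id[i], s)
      wl <- 200:800
      a <- config$a350PerT * Tv * exp(-lat$S[i] * (wl - 350))
      od <- a * 0.01 / 2.303 *
        (1 + stats::rnorm(length(wl), sd = config$odNoise))
      spectra[[i]] <- AbsorptionSpectrum(wl, pmax(od, 0),
                                         pathLength = 0.01, sampleID = id)
      eems[[i]] <- generateEEM(amps, config, season = s,
                               spectrum = spectra[[i]], sampleID = id)
      truthMass[[i]] <- attr(eems[[i]], "truth")
      samp$doc_mg_per_l[i] <- max(0.1, stats::rnorm(1, config$docMean[[s]],
                                                    config$docSd[[s]]))
      samp$chla_ug_per_l[i] <- config$chlaPerA[[s]] * Av *
        exp(stats::rnorm(1, sd = 0.15))
      samp$tp_mg_per_l[i] <- max(0.001, stats::rnorm(
        1, if (s == "JUN") 0.02 else 0.03, 0.004))
      samp$nh3n_mg_per_l[i] <- max(0.001, stats::rnorm(
        1, if (s == "JUN") 0.09 else 0.12, 0.05))
      samp$cod_mg_per_l[i] <- max(1, stats::rnorm(
        1, if (s == "JUN") 28.3 else 22.6, 8))
      samp$ph[i] <- stats::rnorm(1, if (s == "JUN") 8.0 else 7.8, 0.1)
      samp$ec_us_per_cm[i] <- stats::rnorm(
        1, if (s == "JUN") 463.6 else 349.8, 12)
      samp$ism_mg_per_l[i] <- max(0.1, stats::rnorm(
        1, if (s == "JUN") 13.6 else 11.1, 4))
      samp$osm_mg_per_l[i] <- max(0.05, stats::rnorm(
        1, if (s == "JUN") 4.0 else 1.2, 0.8))
      samp$dep_mg_per_l[i] <- max(0.001, config$betaDEP * Tv +
                                    stats::rnorm(1, sd = config$sigmaEps))
      samp$dmp_mg_per_l[i] <- config$dmpPerA[[s]] * Av *
        exp(stats::rnorm(1, sd = 0.25))
      samp$dbp_mg_per_l[i] <- config$dbpMean *
        exp(stats::rnorm(1, sd = 0.4))
    }
    blankI <- .ridge(ex, em, config) +
      matrix(stats::rnorm(length(ex) * length(em), sd = config$noiseSd),
             length(ex))
    blank <- EEMGrid(ex, em, blankI, sampleID = "blank")
    structure(list(
      samples = validateSamples(samp),
      eems = eems, blank = blank, spectra = spectra,
      truth = list(latents = lat, regionMass = truthMass,
                   betaDEP = config$betaDEP, sigmaEps = config$sigmaEps,
                   slopeS = config$slopeS),
      config = config, seed = seed
    ), class = "cohortBundle")
  })
}

#' Write a synthetic survey bundle to disk
#'
#' Emits the same dialects the readers consume: \code{samples.csv} (with
#' \code{eem_file}/\code{abs_file} columns), \code{blank.csv}, one EEM
#' matrix and one absorbance CSV per sample under \code{eem/} and
#' \code{abs/}, and \code{truth.json} with the generator's ground truth.
#'
#' @param bundle a [generateCohort()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
writeCohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohortBundle"))
  dir.create(file.path(dir, "eem"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "abs"), recursive = TRUE, showWarnings = FALSE)
  samp <- bundle$samples
  ids <- vapply(bundle$eems, sampleID, character(1L))
  samp$eem_file <- file.path("eem", paste0(ids, ".csv"))
  samp$abs_file <- file.path("abs", paste0(ids, ".csv"))
  for (i in seq_along(bundle$eems)) {
    writeEEM(bundle$eems[[i]], file.path(dir, samp$eem_file[i]))
    writeAbsorbance(bundle$spectra[[i]], file.path(dir, samp$abs_file[i]))
  }
  writeEEM(bundle$blank, file.path(dir, "blank.csv"))
  writeSamples(samp, file.path(dir, "samples.csv"))
  truth <- bundle$truth
  truth$regionMass <- lapply(truth$regionMass, function(m)
    as.data.frame(m))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
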