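#' @include AllClasses.R
NULL

.preprocessOne <- function(eem, blank, spectrum,
                           halfwidth1 = 15, halfwidth2 = 15,
                           scatterMode = "interpolate", ife = TRUE) {
  out <- subtractBlank(eem, blank)
  if (ife && !is.null(spectrum)) out <- innerFilterCorrect(out, spectrum)
  removeScatter(out, halfwidth1, halfwidth2, mode = scatterMode)
}

#' Analyse a survey (in-memory)
#'
#' Runs the full optical chain on a synthetic bundle or on lists of
#' already-read objects: blank subtraction, inner-filter correction,
#' scatter excision, FRI, fluorescence indices and CDOM absorption
#' metrics, merged with the sample table.
#'
#' @param bundle a [generateCohort()] bundle, or a list with elements
#'   \code{samples}, \code{eems}, \code{blank}, \code{spectra}
#' @param regions region table for FRI
#' @param halfwidth1,halfwidth2,scatterMode,ife preprocessing settings
#'   (see [removeScatter()] and [innerFilterCorrect()])
#' @return data.frame: one row per sample with phi1..phi5, phi_total,
#'   p1..p5, p_allo, the CDOM indices and the sample covariates
#' @export
analyzeCohort <- function(bundle, regions = defaultRegions(),
                          halfwidth1 = 15, halfwidth2 = 15,
                          scatterMode = "interpolate", ife = TRUE) {
  samp <- bundle$samples
  n <- nrow(samp)
  stopifnot(length(bundle$eems) == n, length(bundle$spectra) == n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    eem <- .preprocessOne(bundle$eems[[i]], bundle$blank,
                          bundle$spectra[[i]], halfwidth1, halfwidth2,
                          scatterMode, ife)
    fri <- friComponents(eem, regions)
    idx <- cdomIndices(bundle$spectra[[i]], doc = samp$doc_mg_per_l[i],
                       eem = eem)
    ph <- phi(fri); sh <- regionShares(fri)
    rows[[i]] <- cbind(
      data.frame(site_id = samp$site_id[i], season = samp$season[i]),
      as.data.frame(as.list(ph)),
      phi_total = phiTotal(fri),
      as.data.frame(as.list(sh)),
      p_allo = if (phiTotal(fri) > 0) alloVolume(fri) / phiTotal(fri)
               else NA_real_,
      idx[, setdiff(names(idx), "sample_id"), drop = FALSE]
    )
  }
  optics <- do.call(rbind, rows)
  merge(samp, optics, by = c("site_id", "season"), sort = FALSE)
}

.cfgGet <- function(config, path, default = NULL) {
  node <- config
  for (k in path) {
    if (is.null(node[[k]])) return(default)
    node <- node[[k]]
  }
  node
}

.riskParamsFromConfig <- function(config) {
  rb <- .cfgGet(config, "risk", list())
  rfd <- .cfgGet(rb, "rfd",
                 list(DMP = 1.0, DEP = 0.8, DBP = 0.1))
  for (cg in c("DMP", "DEP", "DBP")) {
    if (is.null(rfd[[cg]])) {
      stop("stage risk: config risk.rfd is missing congener ", cg)
    }
  }
  csf <- unlist(.cfgGet(rb, "csf", list()))
  if (is.null(csf)) csf <- numeric()
  riskParams(dr = .cfgGet(rb, "dr", 2), ef = .cfgGet(rb, "ef", 350),
             ed = .cfgGet(rb, "ed", 30), bw = .cfgGet(rb, "bw", 60),
             at = .cfgGet(rb, "at", 26280),
             rfd = unlist(rfd), csf = csf)
}

#' Run the full pipeline from a YAML configuration
#'
#' Orchestrates preprocess -> FRI/absorption -> PAE composition -> risk
#' -> association on files referenced from a YAML config and writes the
#' results directory: \code{indices.csv} (per-sample FRI volumes, shares
#' and CDOM indices), \code{composition.csv}, \code{risk.csv},
#' \code{correlations.csv} and \code{manifest.json}. Partial outputs are
#' removed on failure. The pipeline is a pure function of (inputs,
#' config), so a rerun reproduces the outputs.
#'
#' Config blocks (all optional except \code{io$samples}):
#' \code{io: {samples, dir, blank}},
#' \code{preprocess: {scatter: {halfwidth1_nm, halfwidth2_nm, mode},
#' ife: {enabled}}}, \code{fri: {regions, multiplication_factors}},
#' \code{risk: {dr, ef, ed, bw, at, rfd: {DMP, DEP, DBP}, csf}},
#' \code{association: {adjust}}. The sample table must carry
#' \code{eem_file} and \code{abs_file} columns (relative to
#' \code{io$dir}, which defaults to the config file's directory).
#'
#' @param config path to a YAML file, or an equivalent named list
#' @param outDir results directory (created)
#' @param force proceed even when preprocessing is disabled (passes
#'   uncorrected EEMs to FRI)
#' @return invisibly, a list with the result tables and file paths
#' @export
runPipeline <- function(config, outDir, force = FALSE) {
  cfgPath <- NULL
  if (is.character(config)) {
    cfgPath <- config
    if (!file.exists(config)) stop("stage config: file not found: ", config)
    config <- yaml::read_yaml(cfgPath)
  }
  baseDir <- .cfgGet(config, c("io", "dir"),
                     if (!is.null(cfgPath)) dirname(cfgPath) else ".")
  sPath <- .cfgGet(config, c("io", "samples"))
  if (is.null(sPath)) stop("stage config: io.samples is required")
  sPath <- file.path(baseDir, sPath)
  if (!file.exists(sPath)) stop("stage dataio: missing input ", sPath)
  samples <- readSamples(sPath)
  for (col in c("eem_file", "abs_file")) {
    if (!col %in% names(samples)) {
      stop("stage dataio: sample table lacks column ", col)
    }
  }
  blankPath <- file.path(baseDir, .cfgGet(config, c("io", "blank"),
                                          "blank.csv"))
  if (!file.exists(blankPath)) {
    stop("stage preprocess: missing blank EEM ", blankPath)
  }
  blank <- readEEM(blankPath)
  eems <- lapply(file.path(baseDir, samples$eem_file), function(p) {
    if (!file.exists(p)) stop("stage dataio: missing EEM file ", p)
    readEEM(p)
  })
  spectra <- lapply(file.path(baseDir, samples$abs_file), function(p) {
    if (!file.exists(p)) stop("stage dataio: missing absorbance file ", p)
    readAbsorbance(p)
  })

  regions <- defaultRegions()
  regPath <- .cfgGet(config, c("fri", "regions"))
  if (!is.null(regPath)) regions <- readRegions(file.path(baseDir, regPath))
  params <- .riskParamsFromConfig(config)

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  outputs <- file.path(outDir, c("indices.csv", "composition.csv",
                                 "risk.csv", "correlations.csv",
                                 "manifest.json"))
  names(outputs) <- c("indices", "composition", "risk", "correlations",
                      "manifest")
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs), add = TRUE)

  indices <- analyzeCohort(
    list(samples = samples, eems = eems, blank = blank, spectra = spectra),
    regions = regions,
    halfwidth1 = .cfgGet(config, c("preprocess", "scatter",
                                   "halfwidth1_nm"), 15),
    halfwidth2 = .cfgGet(config, c("preprocess", "scatter",
                                   "halfwidth2_nm"), 15),
    scatterMode = .cfgGet(config, c("preprocess", "scatter", "mode"),
                          "interpolate"),
    ife = .cfgGet(config, c("preprocess", "ife", "enabled"), TRUE))
  composition <- rbind(paeComposition(samples, "season"),
                       paeComposition(samples, "overall"))
  risk <- riskTable(samples, params)
  assocVars <- intersect(
    c(paste0("phi", 1:5), "fi370", "fi310", "a350_per_m",
      "doc_mg_per_l", "chla_ug_per_l", "dmp_mg_per_l", "dep_mg_per_l",
      "dbp_mg_per_l"),
    names(indices))
  correlations <- pearsonMatrix(
    indices, vars = assocVars,
    adjust = .cfgGet(config, c("association", "adjust"), "none"))

  utils::write.csv(indices, outputs[["indices"]], row.names = FALSE)
  utils::write.csv(composition, outputs[["composition"]],
                   row.names = FALSE)
  utils::write.csv(risk, outputs[["risk"]], row.names = FALSE)
  utils::write.csv(correlations, outputs[["correlations"]],
                   row.names = FALSE)
  manifest <- list(
    package = "cdomPAE",
    version = as.character(utils::packageVersion("cdomPAE")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_md5 = if (!is.null(cfgPath))
      unname(tools::md5sum(cfgPath)) else NA,
    n_samples = nrow(samples),
    outputs = as.list(outputs[1:4]),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, outputs[["manifest"]],
                       auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(list(indices = indices, composition = composition,
                 risk = risk, correlations = correlations,
                 paths = outputs))
}
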