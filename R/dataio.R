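#' @include AllClasses.R
NULL

# Number formatting used by all writers: full double precision so a
# write/read cycle is the identity on values.
.fmt <- function(x) formatC(x, digits = 17, format = "g")

#' Read an EEM matrix file
#'
#' Reads the package's plain-text EEM dialect: a comma-separated matrix
#' whose first row holds the emission wavelengths (nm), first column the
#' excitation wavelengths (nm), and top-left cell a label (ignored).
#' Instruments exporting the transposed layout (excitation across
#' columns) are handled with \code{transpose = TRUE}.
#'
#' @param path file to read
#' @param transpose set TRUE when the file has emission in rows
#' @param sampleID sample identifier; defaults to the file name
#' @return an [EEMGrid-class] with no corrections applied
#' @seealso [writeEEM()]
#' @export
readEEM <- function(path, transpose = FALSE, sampleID = NULL) {
  if (!file.exists(path)) stop("EEM file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("EEM file has no data rows: ", path)
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncol0 <- length(cells[[1L]])
  bad <- which(vapply(cells, length, 1L) != ncol0)
  if (length(bad)) {
    stop(sprintf("ragged EEM file %s: line %d has %d fields, expected %d",
                 path, bad[1L], length(cells[[bad[1L]]]), ncol0))
  }
  em <- as.numeric(cells[[1L]][-1L])
  body <- do.call(rbind, lapply(cells[-1L], function(r) as.numeric(r)))
  ex <- body[, 1L]
  I <- body[, -1L, drop = FALSE]
  if (transpose) {
    tmp <- ex; ex <- em; em <- tmp
    I <- t(I)
  }
  if (anyNA(ex) || any(diff(ex) <= 0)) {
    stop("excitation axis is not strictly increasing in ", path)
  }
  if (anyNA(em) || any(diff(em) <= 0)) {
    stop("emission axis is not strictly increasing in ", path)
  }
  if (is.null(sampleID)) sampleID <- sub("\\.[^.]*$", "", basename(path))
  EEMGrid(ex, em, I, sampleID = sampleID)
}

#' Write an EEM matrix file
#'
#' Inverse of [readEEM()]: emission across columns, excitation down the
#' first column, full double precision.
#'
#' @param eem an [EEMGrid-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeEEM <- function(eem, path) {
  stopifnot(is(eem, "EEMGrid"))
  header <- paste(c("ex_em", .fmt(eem@emission)), collapse = ",")
  rows <- vapply(seq_along(eem@excitation), function(i) {
    paste(c(.fmt(eem@excitation[i]), .fmt(eem@intensity[i, ])),
          collapse = ",")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a UV-Vis absorbance spectrum
#'
#' Two-column CSV (wavelength nm, optical density), optional header row.
#'
#' @param path file to read
#' @param pathLength cuvette path length in metres (default 0.01)
#' @param sampleID sample identifier; defaults to the file name
#' @return an [AbsorptionSpectrum-class]
#' @export
readAbsorbance <- function(path, pathLength = 0.01, sampleID = NULL) {
  if (!file.exists(path)) stop("absorbance file not found: ", path)
  if (length(readLines(path, n = 1L)) == 0L) {
    stop("empty absorbance file: ", path)
  }
  df <- utils::read.csv(path, header = FALSE,
                        colClasses = "character",
                        blank.lines.skip = TRUE)
  if (nrow(df) == 0L) stop("empty absorbance file: ", path)
  if (ncol(df) != 2L) stop("absorbance file must have two columns: ", path)
  # drop a header row if the first cell is non-numeric
  if (is.na(suppressWarnings(as.numeric(df[1L, 1L])))) df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty absorbance file: ", path)
  wl <- as.numeric(df[[1L]])
  od <- as.numeric(df[[2L]])
  if (anyNA(wl) || anyNA(od)) stop("non-numeric values in ", path)
  if (anyDuplicated(wl)) {
    stop("duplicate wavelengths in ", path, ": ",
         paste(unique(wl[duplicated(wl)]), collapse = ", "))
  }
  o <- order(wl)
  if (is.null(sampleID)) sampleID <- sub("\\.[^.]*$", "", basename(path))
  AbsorptionSpectrum(wl[o], od[o], pathLength = pathLength,
                     sampleID = sampleID)
}

#' Write a UV-Vis absorbance spectrum
#'
#' @param spec an [AbsorptionSpectrum-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeAbsorbance <- function(spec, path) {
  stopifnot(is(spec, "AbsorptionSpectrum"))
  writeLines(c("wavelength_nm,od",
               paste(.fmt(spec@wavelength), .fmt(spec@opticalDensity),
                     sep = ",")), path)
  invisible(path)
}

.SAMPLE_NUMERIC <- c("doc_mg_per_l", "chla_ug_per_l", "tp_mg_per_l",
                     "nh3n_mg_per_l", "cod_mg_per_l", "ph", "ec_us_per_cm",
                     "ism_mg_per_l", "osm_mg_per_l",
                     "dmp_mg_per_l", "dep_mg_per_l", "dbp_mg_per_l")
.SEASONS <- c("JUN", "OCT")

#' Validate a survey sample table
#'
#' Checks the per-sample survey table contract: \code{site_id} integer,
#' \code{season} one of JUN/OCT, concentrations non-negative where
#' present (missing water-quality cells stay NA, they are never zero
#' -filled), and site/season pairs unique. Unknown columns are allowed
#' and preserved for the association layer.
#'
#' @param samples data.frame
#' @return the validated data.frame, invisibly unchanged
#' @export
validateSamples <- function(samples) {
  req <- c("site_id", "season")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample table lacks columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(!samples$season %in% .SEASONS)
  if (length(bad)) {
    stop(sprintf("row %d: season '%s' is not one of %s", bad[1L],
                 samples$season[bad[1L]], paste(.SEASONS, collapse = "/")))
  }
  key <- paste(samples$site_id, samples$season)
  if (anyDuplicated(key)) {
    stop("duplicate site_id/season pairs: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  for (col in intersect(.SAMPLE_NUMERIC, names(samples))) {
    v <- samples[[col]]
    neg <- which(!is.na(v) & v < 0 & col != "ph")
    if (length(neg)) {
      stop(sprintf("row %d: negative value %g in column %s",
                   neg[1L], v[neg[1L]], col))
    }
  }
  invisible(samples)
}

#' Read the per-sample survey table
#'
#' CSV with header; required columns \code{site_id} and \code{season}
#' (JUN or OCT); the documented water-quality and PAE columns are
#' numeric; any other columns are kept as-is. Empty cells become NA
#' (explicit missing), never zero. Row order is preserved.
#'
#' @param path CSV file
#' @return validated data.frame of samples
#' @export
readSamples <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  for (col in intersect(.SAMPLE_NUMERIC, names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  validateSamples(df)
  df
}

#' Write the per-sample survey table
#'
#' @param samples data.frame as returned by [readSamples()]
#' @param path output CSV
#' @return invisibly, the path
#' @export
writeSamples <- function(samples, path) {
  validateSamples(samples)
  out <- samples
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && col != "site_id") {
      out[[col]] <- ifelse(is.na(out[[col]]), "", .fmt(out[[col]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
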