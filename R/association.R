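#' @include AllClasses.R
NULL

#' Pairwise Pearson correlation table
#'
#' Pearson product-moment correlations between columns of a numeric
#' table, pairwise-complete, with two-tailed p-values from the
#' t-transform on n - 2 degrees of freedom. Both r and r^2 are reported
#' (composition tables in this field are often labelled R^2 while the
#' text quotes Pearson correlations; emitting both removes the
#' ambiguity). Cells with fewer than \code{minPairs} complete pairs or a
#' zero-variance column are returned as NA with a warning.
#'
#' @param table data.frame of numeric columns
#' @param vars columns to correlate (default: all numeric columns)
#' @param adjust optional p-value adjustment method for
#'   [stats::p.adjust()] (e.g. "BH"); "none" (default) applies none
#' @param minPairs minimum complete pairs per cell (default 3)
#' @return long-format data.frame: var1, var2, n, r, r2, p (and p_adj
#'   when adjustment is requested)
#' @export
pearsonMatrix <- function(table, vars = NULL, adjust = "none",
                          minPairs = 3L) {
  if (is.null(vars)) {
    vars <- names(table)[vapply(table, is.numeric, TRUE)]
  }
  miss <- setdiff(vars, names(table))
  if (length(miss)) stop("columns not found: ", paste(miss, collapse = ", "))
  combos <- utils::combn(vars, 2L)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    v1 <- combos[1L, k]; v2 <- combos[2L, k]
    x <- table[[v1]]; y <- table[[v2]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < minPairs || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning(sprintf("pair (%s, %s): too few pairs or zero variance",
                      v1, v2))
      return(data.frame(var1 = v1, var2 = v2, n = n, r = NA_real_,
                        r2 = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    r <- stats::cor(x[ok], y[ok])
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    data.frame(var1 = v1, var2 = v2, n = n, r = r, r2 = r^2, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!identical(adjust, "none")) {
    out$p_adj <- stats::p.adjust(out$p, method = adjust)
  }
  out
}

#' Simple linear regression of a response on one optical predictor
#'
#' Ordinary least squares of y on x (e.g. DEP concentration on the
#' fulvic-like FRI volume), returning slope, intercept, r^2, the
#' two-tailed slope p-value and a prediction function for new predictor
#' values — the "optical surrogate" use of the regression.
#'
#' @param x predictor values
#' @param y response values
#' @return list: slope, intercept, r.squared, p.value, n, predict
#'   (function of newx)
#' @export
regressSimple <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete (x, y) pairs")
  if (stats::sd(x) == 0) stop("predictor is constant; no fit possible")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  list(
    slope = slope,
    intercept = intercept,
    r.squared = sm$r.squared,
    p.value = unname(sm$coefficients[2L, 4L]),
    n = length(x),
    predict = function(newx) intercept + slope * newx
  )
}

#' One-way analysis of variance
#'
#' Classical one-way ANOVA F-test across two or more groups (e.g. the
#' June versus October campaigns). The degenerate case of all values
#' identical returns F = 0 and p = 1 instead of 0/0.
#'
#' @param groups list of numeric vectors, each with at least 2 values
#' @return list with \code{F} and \code{p}
#' @export
anovaOneway <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  ns <- vapply(groups, function(g) sum(is.finite(g)), 1L)
  if (any(ns < 2L)) stop("each group needs at least 2 values")
  y <- unlist(lapply(groups, function(g) g[is.finite(g)]))
  g <- factor(rep(seq_along(groups), ns))
  if (stats::sd(y) == 0) return(list(F = 0, p = 1))
  tab <- stats::anova(stats::lm(y ~ g))
  list(F = unname(tab[["F value"]][1L]), p = unname(tab[["Pr(>F)"]][1L]))
}
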