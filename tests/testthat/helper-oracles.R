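# Independent brute-force oracles used across test files. These stay
# deliberately naive (double loops, explicit sums) so they cannot share
# a defect with the vectorised implementation.

# cell-by-cell scatter band classification
oracleScatterBand <- function(ex, em, w1, w2) {
  out <- matrix(FALSE, length(ex), length(em))
  for (i in seq_along(ex)) {
    for (j in seq_along(em)) {
      out[i, j] <- abs(em[j] - ex[i]) <= w1 || abs(em[j] - 2 * ex[i]) <= w2
    }
  }
  out
}

# region id per grid cell under the half-open convention (0 = none)
oracleRegionAssignment <- function(ex, em, regions) {
  out <- matrix(0L, length(ex), length(em))
  for (i in seq_along(ex)) {
    for (j in seq_along(em)) {
      for (r in seq_len(nrow(regions))) {
        if (ex[i] >= regions$ex_low[r] && ex[i] < regions$ex_high[r] &&
            em[j] >= regions$em_low[r] && em[j] < regions$em_high[r]) {
          out[i, j] <- out[i, j] * 100L + r  # flags double-assignment
        }
      }
    }
  }
  out
}

# Riemann volume of one region by explicit double loop
oracleRegionVolume <- function(I, ex, em, region, dex, dem) {
  v <- 0
  for (i in seq_along(ex)) {
    for (j in seq_along(em)) {
      if (ex[i] >= region$ex_low && ex[i] < region$ex_high &&
          em[j] >= region$em_low && em[j] < region$em_high) {
        v <- v + I[i, j] * dex * dem
      }
    }
  }
  v
}

# Pearson r by explicit summation
oraclePearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# one-way ANOVA F by explicit sums of squares
oracleAnovaF <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# small uniform EEM on arbitrary axes, marked fully corrected
uniformEEM <- function(ex, em, value = 1) {
  EEMGrid(ex, em, matrix(value, length(ex), length(em)),
          sampleID = "uniform",
          correctionsApplied = c("blank", "scatter"))
}

defaultGridEEM <- function(I, corrections = c("blank", "scatter")) {
  EEMGrid(seq(220, 450, 5), 250:600, I, sampleID = "test",
          correctionsApplied = corrections)
}
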