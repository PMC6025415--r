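test_that("blank subtraction floors negatives and logs the count", {
  ex <- c(220, 225, 230); em <- 300:305
  mk <- function(v) EEMGrid(ex, em, matrix(v, 3, 6))
  expect_equal(intensity(subtractBlank(mk(2), mk(2))),
               matrix(0, 3, 6))
  expect_equal(intensity(subtractBlank(mk(5), mk(2))),
               matrix(3, 3, 6))
  floored <- subtractBlank(mk(1), mk(2))
  expect_equal(intensity(floored), matrix(0, 3, 6))
  expect_equal(attr(floored, "flooredCells"), 18L)
  expect_true("blank" %in% correctionsApplied(floored))
  # mixed case: only the negative cells are floored
  I <- matrix(c(5, 1), 3, 6)
  part <- subtractBlank(EEMGrid(ex, em, I), mk(2))
  expect_equal(attr(part, "flooredCells"), sum(I < 2))
  expect_error(subtractBlank(mk(1), EEMGrid(ex + 1, em, matrix(0, 3, 6))),
               "axes")
})

test_that("scatter band membership matches an exhaustive double-loop oracle", {
  ex <- seq(220, 450, 5); em <- 250:600
  eem <- defaultGridEEM(matrix(runif(47 * 351), 47, 351))
  zeroed <- removeScatter(eem, 15, 15, mode = "zero")
  band <- oracleScatterBand(ex, em, 15, 15)
  expect_identical(excisedMask(zeroed), band)
  expect_true(all(intensity(zeroed)[band] == 0))
  # cells outside both bands are bit-identical
  expect_identical(intensity(zeroed)[!band], intensity(eem)[!band])
  # asymmetric halfwidths
  band2 <- oracleScatterBand(ex, em, 10, 25)
  z2 <- removeScatter(eem, 10, 25, mode = "zero")
  expect_identical(excisedMask(z2), band2)
})

test_that("interpolation refills excised bands, zero-anchored at edges", {
  # small grid where the bands are easy to enumerate
  ex <- c(260, 280, 300, 320, 340)
  em <- seq(250, 430, by = 20)
  eem <- EEMGrid(ex, em, matrix(1, 5, 10))
  out <- removeScatter(eem, 15, 15, mode = "interpolate")
  band <- oracleScatterBand(ex, em, 15, 15)
  I <- intensity(out)
  for (i in seq_along(ex)) {
    cut <- band[i, ]
    runs <- rle(cut)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in seq_along(runs$values)) {
      if (!runs$values[k]) next
      touchesEdge <- starts[k] == 1L || ends[k] == length(em)
      if (touchesEdge) {
        # ramp from the zero anchor: strictly below the plateau
        expect_true(all(I[i, starts[k]:ends[k]] < 1))
      } else {
        # interior gap on a uniform EEM interpolates back to 1
        expect_equal(I[i, starts[k]:ends[k]],
                     rep(1, runs$lengths[k]))
      }
    }
    expect_equal(I[i, !cut], rep(1, sum(!cut)))
  }
  expect_true("scatter" %in% correctionsApplied(out))
})

test_that("a pure first-order ridge is wiped by zero-mode excision", {
  ex <- seq(250, 400, 5)
  em <- seq(250, 420, 1)
  I <- outer(ex, em, function(x, m) 100 * (abs(m - x) < 1e-9))
  eem <- EEMGrid(ex, em, I)
  out <- removeScatter(eem, 15, 15, mode = "zero")
  expect_true(all(intensity(out) == 0))
})

test_that("inner-filter correction applies 10^((Aex+Aem)/2) cellwise", {
  ex <- c(300, 310); em <- c(400, 410, 420)
  eem <- EEMGrid(ex, em, matrix(10, 2, 3))
  flat0 <- AbsorptionSpectrum(250:500, rep(0, 251))
  expect_equal(intensity(innerFilterCorrect(eem, flat0)), matrix(10, 2, 3))

  # A(ex) = 0.12, A(em) = 0.08 -> factor 10^0.1
  od <- ifelse(250:500 <= 350, 0.12, 0.08)
  spec <- AbsorptionSpectrum(250:500, od)
  corr <- innerFilterCorrect(eem, spec)
  expect_equal(intensity(corr), matrix(10 * 10^0.1, 2, 3),
               tolerance = 1e-12)
  expect_equal(intensity(corr)[1, 1], 12.589, tolerance = 1e-4)

  # doubling OD squares the correction factor at each cell
  spec2 <- AbsorptionSpectrum(250:500, 2 * od)
  f1 <- intensity(innerFilterCorrect(eem, spec)) / intensity(eem)
  f2 <- intensity(innerFilterCorrect(eem, spec2)) / intensity(eem)
  expect_equal(f2, f1^2, tolerance = 1e-12)

  # monotone: larger OD never decreases any intensity
  expect_true(all(intensity(innerFilterCorrect(eem, spec2)) >=
                    intensity(innerFilterCorrect(eem, spec))))

  # no extrapolation outside the measured absorbance range
  short <- AbsorptionSpectrum(350:500, rep(0.1, 151))
  expect_error(innerFilterCorrect(eem, short), "cover")
})

test_that("corrections are order-logged and FRI refuses uncorrected EEMs", {
  ex <- seq(220, 450, 5); em <- 250:600
  eem <- EEMGrid(ex, em, matrix(1, 47, 351))
  expect_error(friComponents(eem), "lacks corrections")
  expect_error(integrateRegion(eem, defaultRegions()[1, ]), "blank")
  expect_silent(friComponents(eem, force = TRUE))
  blank <- EEMGrid(ex, em, matrix(0, 47, 351))
  done <- removeScatter(subtractBlank(eem, blank))
  expect_setequal(correctionsApplied(done), c("blank", "scatter"))
  expect_s4_class(friComponents(done), "FRIResult")
})
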