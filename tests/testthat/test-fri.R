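test_that("regional volumes match counted-cell values on a uniform EEM", {
  eem <- uniformEEM(seq(220, 450, 5), 250:600)
  regions <- defaultRegions()
  # R1 clipped to the grid: ex {220..245} (6 points) x em {280..329}
  # (50 points) x 5 nm x 1 nm
  expect_equal(integrateRegion(eem, regions[1, ]), 6 * 50 * 5)
  # counted-cell expectations for all five clipped regions
  counts <- c(6 * 50, 6 * 50, 6 * 170, 30 * 100, 30 * 170)
  vols <- vapply(1:5, function(r) integrateRegion(eem, regions[r, ]), 1)
  expect_equal(vols, counts * 5)
  # against the double-loop oracle
  oracle <- vapply(1:5, function(r)
    oracleRegionVolume(intensity(eem), excitation(eem), emission(eem),
                       regions[r, ], 5, 1), 1)
  expect_equal(vols, oracle)
})

test_that("integration is linear and zero on empty EEMs", {
  ex <- seq(220, 450, 5); em <- 250:600
  zero <- uniformEEM(ex, em, 0)
  regions <- defaultRegions()
  for (r in 1:5) expect_equal(integrateRegion(zero, regions[r, ]), 0)
  set.seed(42)
  I <- matrix(rexp(47 * 351), 47, 351)
  e1 <- defaultGridEEM(I)
  e3 <- defaultGridEEM(3.7 * I)
  for (r in 1:5) {
    expect_equal(integrateRegion(e3, regions[r, ]),
                 3.7 * integrateRegion(e1, regions[r, ]),
                 tolerance = 1e-12)
  }
  # irregular axis spacing is refused
  bad <- EEMGrid(c(220, 225, 235), 300:310, matrix(1, 3, 11),
                 correctionsApplied = c("blank", "scatter"))
  expect_error(integrateRegion(bad, regions[4, ]), "resample")
})

test_that("half-open regions partition the grid (exhaustive oracle)", {
  ex <- seq(220, 450, 5); em <- 250:600
  assign <- oracleRegionAssignment(ex, em, defaultRegions())
  # no cell in more than one region
  expect_true(all(assign <= 5L))
  # shares on a uniform EEM are proportional to assigned cell counts
  eem <- uniformEEM(ex, em)
  fri <- friComponents(eem)
  counts <- vapply(1:5, function(r) sum(assign == r), 1L)
  expect_equal(unname(regionShares(fri)), counts / sum(counts),
               tolerance = 1e-12)
  expect_equal(sum(regionShares(fri)), 1)
  # Sum of Phi_i plus the unassigned volume equals the whole-grid volume
  expect_equal(phiTotal(fri) + unassignedVolume(fri),
               sum(intensity(eem)) * 5 * 1, tolerance = 1e-12)
  # allo + auto decomposition
  expect_equal(alloVolume(fri) + autoVolume(fri), phiTotal(fri))
  expect_equal(alloVolume(fri), sum(phi(fri)[c(3, 5)]))
})

test_that("volumes are invariant to zero-padding outside the regions", {
  ex <- seq(220, 450, 5); em <- 250:600
  set.seed(7)
  I <- matrix(rexp(47 * 351), 47, 351)
  base <- friComponents(defaultGridEEM(I))
  # extend the emission axis with all-zero columns beyond 600 nm
  em2 <- 250:650
  I2 <- cbind(I, matrix(0, 47, 50))
  padded <- friComponents(EEMGrid(ex, em2, I2,
                                  correctionsApplied = c("blank", "scatter")))
  expect_equal(phi(padded), phi(base), tolerance = 1e-12)
})

test_that("an EEM confined to one region yields share 1 for it", {
  ex <- seq(220, 450, 5); em <- 250:600
  I <- matrix(0, 47, 351)
  inEx <- ex >= 250 & ex < 400
  inEm <- em >= 380 & em < 550
  I[inEx, inEm] <- 2.5
  fri <- friComponents(defaultGridEEM(I))
  expect_equal(unname(regionShares(fri)[5]), 1)
  expect_equal(alloVolume(fri), phiTotal(fri))
  # all-zero EEM: shares undefined with a warning
  expect_warning(z <- friComponents(uniformEEM(ex, em, 0)), "zero")
  expect_true(all(is.na(regionShares(z))))
})

test_that("Riemann volumes agree with analytic truncated Gaussian masses", {
  cfg <- cohortConfig(noiseSd = 0, ridgeAmplitude = 0)
  amps <- c(R1 = 120, R2 = 90, R3 = 400, R4 = 260, R5 = 610)
  eem <- generateEEM(amps, cfg, season = "JUN", ridge = FALSE,
                     noise = FALSE)
  truth <- attr(eem, "truth")
  eem@correctionsApplied <- c("blank", "scatter")
  fri <- friComponents(eem)
  expected <- colSums(truth)  # every fluorophore's mass in each region
  expect_equal(unname(phi(fri)), unname(expected), tolerance = 0.02)
})

test_that("fluorescence indices are the stated emission ratios", {
  ex <- seq(220, 450, 5); em <- 250:600
  I <- matrix(1, 47, 351)
  iex370 <- which(ex == 370); iex310 <- which(ex == 310)
  I[iex370, em == 450] <- 2.0
  I[iex370, em == 500] <- 1.0
  I[iex310, em == 380] <- 0.9
  I[iex310, em == 430] <- 1.2
  eem <- defaultGridEEM(I)
  expect_equal(fluorescenceIndex(eem, "FI370"), 2.0)
  expect_equal(fluorescenceIndex(eem, "FI310"), 0.75)
  # identity case
  expect_equal(fluorescenceIndex(defaultGridEEM(matrix(1, 47, 351)),
                                 "FI370"), 1)
  # nonpositive denominator -> NA with warning
  I[iex370, em == 500] <- 0
  expect_warning(v <- fluorescenceIndex(defaultGridEEM(I), "FI370"),
                 "denominator")
  expect_true(is.na(v))
  # excised cell -> error suggesting interpolation
  zeroed <- removeScatter(defaultGridEEM(matrix(1, 47, 351), "blank"),
                          80, 15, mode = "zero")
  expect_error(fluorescenceIndex(zeroed, "FI370"), "interpolate")
  # off-grid wavelength
  small <- uniformEEM(seq(220, 300, 5), 250:400)
  expect_error(fluorescenceIndex(small, "FI370"), "not on the measured grid")
})

test_that("source classification applies the published thresholds", {
  expect_equal(classifySource(1.14, 0.81),
               list(fulvic = "terrestrial",
                    autochthonous = "autochthonous-high"))
  expect_equal(classifySource(2.0, 0.5),
               list(fulvic = "microbial",
                    autochthonous = "autochthonous-low"))
  # inclusive boundary handling
  expect_equal(classifySource(1.4, 0.7),
               list(fulvic = "intermediate",
                    autochthonous = "autochthonous-intermediate"))
  expect_equal(classifySource(1.9, 0.8),
               list(fulvic = "intermediate",
                    autochthonous = "autochthonous-intermediate"))
  expect_true(is.na(classifySource(NA, 0.5)$fulvic))
})

test_that("region tables round-trip through YAML and reject bad bounds", {
  d <- withr::local_tempdir()
  p <- file.path(d, "regions.yaml")
  writeRegions(defaultRegions(), p)
  back <- readRegions(p)
  expect_equal(back$ex_low, defaultRegions()$ex_low)
  expect_equal(back$label, defaultRegions()$label)
  bad <- defaultRegions()
  bad$ex_high[1] <- bad$ex_low[1]
  expect_error(writeRegions(bad, p), "low < high")
})
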