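test_that("cohort generation is deterministic and matches the design", {
  cfg <- cohortConfig()
  b1 <- generateCohort(cfg, seed = 1)
  b2 <- generateCohort(cfg, seed = 1)
  expect_identical(b1$samples, b2$samples)
  expect_identical(intensity(b1$eems[[1]]), intensity(b2$eems[[1]]))
  expect_identical(opticalDensity(b1$spectra[[45]]),
                   opticalDensity(b2$spectra[[45]]))
  expect_identical(intensity(b1$blank), intensity(b2$blank))
  b3 <- generateCohort(cfg, seed = 2)
  expect_false(identical(b1$samples$dep_mg_per_l,
                         b3$samples$dep_mg_per_l))
  expect_equal(nrow(b1$samples), 45L)
  expect_equal(sum(b1$samples$season == "JUN"), 25L)
  expect_equal(sum(b1$samples$season == "OCT"), 20L)
  expect_true(all(b1$samples$dep_mg_per_l > 0))
})

test_that("generateEEM with zero amplitudes and no noise is empty", {
  cfg <- cohortConfig()
  amps <- c(R1 = 0, R2 = 0, R3 = 0, R4 = 0, R5 = 0)
  eem <- generateEEM(amps, cfg, ridge = FALSE, noise = FALSE)
  expect_true(all(intensity(eem) == 0))
  # same seed -> identical EEM
  e1 <- generateEEM(c(R1 = 1, R2 = 1, R3 = 1, R4 = 1, R5 = 1), cfg,
                    seed = 42)
  e2 <- generateEEM(c(R1 = 1, R2 = 1, R3 = 1, R4 = 1, R5 = 1), cfg,
                    seed = 42)
  expect_identical(intensity(e1), intensity(e2))
})

test_that("a lone fulvic-like fluorophore concentrates in region 3", {
  cfg <- cohortConfig()
  eem <- generateEEM(c(R1 = 0, R2 = 0, R3 = 500, R4 = 0, R5 = 0), cfg,
                     ridge = FALSE, noise = FALSE)
  fri <- friComponents(eem, force = TRUE)
  expect_gte(unname(regionShares(fri)[3]), 0.95)
})

test_that("FRI shares recover the generator's analytic masses within 5%", {
  cfg <- cohortConfig()
  b <- generateCohort(cfg, seed = 4)
  res <- analyzeCohort(b)
  for (i in c(1, 20, 30, 45)) {
    truth <- b$truth$regionMass[[i]]
    trueShare <- colSums(truth) / sum(truth)
    got <- unlist(res[i, paste0("p", 1:5)])
    expect_lt(max(abs(got - trueShare)), 0.05)
  }
})

test_that("the pipeline recovers the generating spectral slopes", {
  cfg <- cohortConfig()
  b <- generateCohort(cfg, seed = 5)
  res <- analyzeCohort(b)
  for (s in c("JUN", "OCT")) {
    err <- abs(res$s275_295_per_nm[res$season == s] - cfg$slopeS[[s]])
    expect_lt(max(err), 0.001)
  }
})

test_that("June cohorts hit the FI370 calibration target", {
  cfg <- cohortConfig()
  b <- generateCohort(cfg, seed = 1)
  res <- analyzeCohort(b)
  expect_lt(abs(mean(res$fi370[res$season == "JUN"]) - 1.39), 0.05)
  expect_lt(abs(mean(res$fi370[res$season == "OCT"]) - 1.14), 0.05)
})

test_that("October shifts raise the allochthonous share (multi-seed)", {
  cfg <- cohortConfig()
  diffs <- vapply(1:5, function(s) {
    res <- analyzeCohort(generateCohort(cfg, seed = s))
    mean(res$p_allo[res$season == "OCT"]) -
      mean(res$p_allo[res$season == "JUN"])
  }, 1)
  expect_true(all(diffs > 0))
})

test_that("FRI-PAE correlation strength follows the loading order", {
  cfg <- cohortConfig()
  ord <- vapply(1:5, function(s) {
    res <- analyzeCohort(generateCohort(cfg, seed = s))
    r <- abs(c(cor(res$phi3, res$dep_mg_per_l),
               cor(res$phi4, res$dep_mg_per_l),
               cor(res$phi5, res$dep_mg_per_l)))
    r[1] >= r[2] && r[2] > r[3]
  }, TRUE)
  expect_true(all(ord))
})

test_that("written bundles are byte-reproducible and readable", {
  cfg <- cohortConfig()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeCohort(generateCohort(cfg, seed = 8), d1)
  writeCohort(generateCohort(cfg, seed = 8), d2)
  for (f in c("samples.csv", "blank.csv", "eem/site01_JUN.csv",
              "abs/site20_OCT.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  }
  s <- readSamples(file.path(d1, "samples.csv"))
  expect_equal(nrow(s), 45L)
  expect_true(all(file.exists(file.path(d1, s$eem_file))))
  expect_true(all(file.exists(file.path(d1, s$abs_file))))
})

test_that("unattainable correlation targets are refused", {
  expect_error(cohortConfig(r2Target = 0.999,
                            amplitudeJitterSd = c(R1 = 0.2, R2 = 0.2,
                                                  R3 = 0.5, R4 = 0.1,
                                                  R5 = 0.4)),
               "unattainable")
})
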