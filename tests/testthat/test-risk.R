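test_that("average daily dose follows (C DR EF ED)/(BW AT)", {
  p <- riskParams()
  expect_equal(averageDailyDose(0, p), 0)
  # October DEP mean, default adult scenario
  expect_equal(averageDailyDose(0.533, p),
               0.533 * 2 * 350 * 30 / (60 * 26280), tolerance = 1e-12)
  expect_equal(averageDailyDose(0.533, p), 7.099e-3, tolerance = 1e-4)
  # doubling body weight halves the dose; linear in C
  p2 <- riskParams(bw = 120)
  expect_equal(averageDailyDose(1, p2), averageDailyDose(1, p) / 2)
  expect_equal(averageDailyDose(2.5, p), 2.5 * averageDailyDose(1, p))
  # strict averaging-time mode recomputes AT = ED * 365
  ps <- riskParams(strictAveragingTime = TRUE)
  expect_equal(ps@at, 30 * 365)
})

test_that("hazard quotient and index with classification", {
  expect_equal(hazardQuotient(0.8, rfd = 0.8), 1)
  expect_equal(hazardQuotient(7.099e-3, rfd = 0.8), 8.87e-3,
               tolerance = 1e-3)
  expect_equal(hazardQuotient(0, rfd = 0.1), 0)
  expect_error(hazardQuotient(1, congener = "DEHP"), "DEHP")
  hi <- hazardIndex(c(0.2, 0.3))
  expect_equal(hi$hi, 0.5)
  expect_equal(hi$classification, "low non-cancer risk")
  expect_equal(hazardIndex(2)$classification, "high non-cancer risk")
  expect_equal(hazardIndex(c(0.5, 0.5))$classification, "boundary")
  expect_error(hazardIndex(numeric()), "no hazard quotients")
})

test_that("seasonal-average means give HI 7.77e-3, low risk", {
  res <- assessRisk(c(DMP = 0.01, DEP = 0.403, DBP = 0.007))
  k <- 2 * 350 * 30 / (60 * 26280)
  expect_equal(unname(hazardQuotients(res)),
               c(0.01 * k / 1.0, 0.403 * k / 0.8, 0.007 * k / 0.1),
               tolerance = 1e-12)
  expect_equal(hazardIndexValue(res), 7.77e-3, tolerance = 1e-3)
  expect_equal(riskClassification(res), "low non-cancer risk")
  expect_equal(res@tier, "not-evaluated")
  expect_error(assessRisk(c(DEHP = 0.1)), "DEHP")
})

test_that("carcinogenic branch computes CR and tiers RI", {
  expect_equal(carcinogenicRisk(1e-3, 1e-2), 1e-5)
  expect_equal(riskIndex(1e-5)$tier, "intermediate")
  expect_equal(riskIndex(0)$tier, "very low")
  expect_equal(riskIndex(c(9e-5, 2e-5))$tier, "unacceptable")
  p <- riskParams(csf = c(DEP = 1e-2))
  res <- assessRisk(c(DEP = 0.1), p)
  expect_equal(unname(res@cr), averageDailyDose(0.1, p) * 1e-2)
  expect_false(res@tier == "not-evaluated")
})

test_that("HQ stays below 1 for any C <= 1 mg/L with RfD >= 0.1", {
  p <- riskParams()
  conc <- seq(0, 1, length.out = 101)
  hq <- hazardQuotient(averageDailyDose(conc, p), rfd = 0.1)
  expect_true(all(hq < 1))
})

test_that("composition statistics reproduce weighted shares", {
  jun <- c(DMP = 0.013, DEP = 0.299, DBP = 0.006)
  oct <- c(DMP = 0.006, DEP = 0.533, DBP = 0.007)
  samples <- data.frame(
    site_id = c(1:25, 1:20),
    season = rep(c("JUN", "OCT"), c(25, 20)),
    dmp_mg_per_l = rep(c(jun[1], oct[1]), c(25, 20)),
    dep_mg_per_l = rep(c(jun[2], oct[2]), c(25, 20)),
    dbp_mg_per_l = rep(c(jun[3], oct[3]), c(25, 20)))
  bySeason <- paeComposition(samples, "season")
  junRows <- bySeason[bySeason$group == "JUN", ]
  expect_equal(unique(junRows$sum3paes_mg_per_l), 0.318)
  expect_equal(junRows$share_pct[junRows$congener == "DEP"],
               100 * 0.299 / 0.318)
  # shares sum to 100 within each group
  expect_equal(unname(as.numeric(
    tapply(bySeason$share_pct, bySeason$group, sum))),
    c(100, 100), tolerance = 1e-9)
  overall <- paeComposition(samples, "overall")
  expect_equal(overall$mean_mg_per_l[overall$congener == "DEP"],
               (25 * 0.299 + 20 * 0.533) / 45, tolerance = 1e-12)
  expect_equal(overall$n, rep(45L, 3))
  # single congener dominates completely
  one <- samples
  one$dmp_mg_per_l <- 0; one$dbp_mg_per_l <- 0
  shares <- paeComposition(one, "overall")$share_pct
  expect_equal(shares, c(0, 100, 0))
  expect_error(paeShares(c(DMP = 0, DEP = 0, DBP = 0)), "positive")
})

test_that("per-site risk table classifies every sample", {
  b <- generateCohort(cohortConfig(), seed = 3)
  rt <- riskTable(b$samples)
  expect_equal(nrow(rt), 45L)
  expect_equal(rt$hi, rt$hq_dmp + rt$hq_dep + rt$hq_dbp,
               tolerance = 1e-12)
  expect_true(all(rt$hi >= 0))
  expect_true(all(rt$classification %in%
                    c("low non-cancer risk", "high non-cancer risk",
                      "boundary")))
})
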