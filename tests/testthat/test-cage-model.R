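test_that("trial protocols encode the experimental schedules", {
  p <- buildProtocol("trial23", "ratio_3_1")
  est <- p@establishment
  expect_equal(nrow(est), 8)
  expect_true(all(est$females == 50 & est$males == 50))
  expect_true(all(est$day %% 7 %in% c(1, 4)))   # Tue/Fri additions
  expect_equal(p@releaseSize, 150)
  expect_equal(p@releaseStart, 28)
  expect_equal(p@durationDays, 148)

  ctrl <- buildProtocol("trial23", "control")
  expect_equal(ctrl@establishment, est)
  expect_equal(ctrl@releaseSize, 0)

  p1 <- buildProtocol("trial1", "ratio_1_1")
  e1 <- p1@establishment
  expect_equal(e1$day[1], 0)
  expect_equal(e1$females[1], 300)
  expect_equal(e1$males[1], 178)
  expect_true(e1$stationary[1])
  expect_equal(sum(e1$females[e1$females == 60]), 360)  # 6 x 60
  expect_equal(sum(e1$females[e1$females == 50]), 300)  # 6 x 50
  expect_equal(p1@releaseSize, 50)
  expect_equal(p1@releaseStart, 42)
  expect_equal(p1@durationDays, 102)
})

test_that("cage runs are deterministic under a fixed seed", {
  p <- buildProtocol("trial23", "control", postReleaseDays = 14)
  a <- runCage(p, seed = 4)
  b <- runCage(p, seed = 4)
  expect_identical(samples(a), samples(b))
  expect_identical(census(a), census(b))
  c <- runCage(p, seed = 5)
  expect_false(identical(samples(a), samples(c)))
})

test_that("an all-wild-type cage is an absorbing state for the transgene", {
  s <- runCage(buildProtocol("trial23", "control"), seed = 8)
  expect_true(all(samples(s)$restock_transgenic == 0))
  tf <- samples(s)$transgene_freq
  expect_true(all(tf[!is.na(tf)] == 0))
  expect_true(all(census(s)$transgenic_adults == 0))
})

test_that("mating picks uniformly among living males", {
  set.seed(31)
  pool <- c(rep("HEMI", 50), rep("WT", 50))
  mates <- mateFemale(rep("WT", 1e4), pool)
  expect_equal(mean(mates == "HEMI"), 0.5, tolerance = 0.015 / 0.5)
  expect_true(all(mateFemale(rep("WT", 20), rep("WT", 3)) == "WT"))
  expect_identical(mateFemale(c("WT", "HEMI"), character(0)), character(0))
})

test_that("restock sampling is hypergeometric and conserves eggs", {
  pool <- emptyBrood()
  pool["WT", "F"] <- 60; pool["WT", "M"] <- 40
  expect_equal(sampleRestock(pool, 100), pool)   # exhaustive sample
  small <- emptyBrood(); small["HEMI", "M"] <- 40
  expect_equal(sum(sampleRestock(small, 100)), 40)  # undersized pool kept

  big <- emptyBrood()
  big["WT", "F"] <- 300; big["WT", "M"] <- 500; big["HEMI", "M"] <- 200
  set.seed(32)
  fem <- replicate(1e4, sum(sampleRestock(big, 100)[, "F"]))
  expect_equal(mean(fem), 30, tolerance = 0.5 / 30)   # hypergeometric mean
  expect_true(all(replicate(50, sum(sampleRestock(big, 100))) == 100))
  expect_error(sampleRestock(big, 0), "positive")
})

test_that("mean-field equilibrium solves the release-balance quadratic", {
  eq0 <- meanFieldEquilibrium(200, 0)
  expect_equal(eq0$p, 0); expect_equal(eq0$F, 0.5); expect_equal(eq0$q, 0)
  # reference roots computed independently; printed to 3-4 decimals
  eq1 <- meanFieldEquilibrium(200, 100)
  expect_equal(eq1$p, 0.6214, tolerance = 1e-4)
  expect_equal(eq1$F, 0.220, tolerance = 0.005)
  expect_equal(eq1$q, 0.311, tolerance = 0.005)
  eq3 <- meanFieldEquilibrium(200, 300)
  expect_equal(eq3$p, 0.7964, tolerance = 1e-4)
  expect_equal(eq3$F, 0.142, tolerance = 0.005)
  expect_equal(eq3$q, 0.398, tolerance = 0.005)
  # root actually satisfies the quadratic
  with(eq1, expect_equal(0.45 * 200 * p^2 + (0.025 * 200 + 100) * p - 100,
                         0, tolerance = 1e-10))
  expect_error(meanFieldEquilibrium(0, 10), "positive")
})

test_that("single-run observables behave as expected by treatment", {
  ctrl <- runCage(buildProtocol("trial23", "control"), seed = 40)
  p45 <- post45Summary(ctrl)
  pf <- p45$mean[p45$variable == "prop_female"]
  expect_gt(pf, 0.45); expect_lt(pf, 0.55)

  s31 <- runCage(buildProtocol("trial23", "ratio_3_1"), seed = 40)
  pf31 <- post45Summary(s31)$mean[1]
  expect_lt(pf31, pf)

  s11 <- runCage(buildProtocol("trial23", "ratio_1_1"), seed = 40)
  sam <- samples(s11)
  rel <- sam[sam$day >= 28, ]
  expect_lt(trendSlope(rel$day, rel$eggs_laid)$slope, 0)
})

test_that("egg bookkeeping is conserved", {
  s <- runCage(buildProtocol("trial23", "ratio_1_1"), seed = 41)
  sam <- samples(s)
  expect_true(all(sam$restock_total <= pmin(100, sam$eggs_laid)))
  expect_true(all(sam$restock_female + sam$restock_male == sam$restock_total))
  expect_true(all(sam$eggs_laid >= 0))
})
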