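test_that("Weibull survival closed forms hold", {
  m <- lifespanModel(shape = 1, scale = 10, sex = "male")
  expect_equal(weibullSurvival(0, m), 1)
  expect_equal(weibullSurvival(10, m), exp(-1))
  for (shape in c(0.8, 1, 2, 4)) {
    mm <- lifespanModel(shape, 17.3)
    expect_equal(weibullSurvival(medianLifespan(mm), mm), 0.5)
    s <- weibullSurvival(seq(0, 80, by = 0.5), mm)
    expect_true(all(diff(s) < 0))
    expect_true(all(s > 0 & s <= 1))
  }
  expect_error(weibullSurvival(-1, m), "non-negative")
})

test_that("default lifespans reproduce the experimental medians", {
  d <- defaultLifespans()
  expect_equal(medianLifespan(d$male), 28)
  expect_equal(medianLifespan(d$female), 30)
  expect_gt(medianLifespan(d$female), medianLifespan(d$male))
  expect_equal(d$male@scale, 28 / log(2)^0.25, tolerance = 1e-12)
  expect_equal(d$male@scale, 30.69, tolerance = 1e-3)
  # nearly everyone dead by the 42-day censor point
  expect_lt(weibullSurvival(42, d$male), 0.05)
  expect_lt(weibullSurvival(42, d$female), 0.08)
})

test_that("lifespan sampling matches closed forms and is reproducible", {
  d <- defaultLifespans()
  set.seed(5)
  x <- sampleLifespan(1e5, d$male)
  expect_true(all(x >= 0))
  expect_equal(median(x), 28, tolerance = 0.01)
  # near-degenerate shape concentrates at the scale
  set.seed(6)
  y <- sampleLifespan(1e4, lifespanModel(200, 30))
  expect_true(all(abs(y - 30) / 30 < 0.05))
  expect_lt(sd(y) / 30, 0.01)   # draws concentrate at the scale
  set.seed(7); a <- sampleLifespan(1, d$female)
  set.seed(7); b <- sampleLifespan(1, d$female)
  expect_identical(a, b)
})

test_that("censored Weibull fit recovers generating parameters", {
  d <- defaultLifespans()
  dd <- genSurvivalExperiment(d, cages = 12, nPerSexPerCage = 30, seed = 21)
  fitM <- fitWeibullCensored(dd, sex = "M")
  expect_equal(medianLifespan(fitM), 28, tolerance = 1.5 / 28)
  fitF <- fitWeibullCensored(dd, sex = "F")
  expect_equal(medianLifespan(fitF), 30, tolerance = 1.5 / 30)
  expect_gt(fitM@shape, 0)
  expect_gt(fitM@scale, 0)
})

test_that("exponential special case recovers shape 1 at larger n", {
  exp10 <- list(male = lifespanModel(1, 10, "male"),
                female = lifespanModel(1, 10, "female"))
  # ~2000 individuals per sex; censor far out so most deaths observed
  dd <- genSurvivalExperiment(exp10, cages = 34, nPerSexPerCage = 60,
                              censorDay = 60, seed = 22)
  fit <- fitWeibullCensored(dd, sex = "M")
  expect_equal(fit@shape, 1, tolerance = 0.15)
})

test_that("fit-sample round trip recovers parameters", {
  start <- lifespanModel(3, 25, "female")
  dd <- genSurvivalExperiment(list(male = start, female = start),
                              cages = 20, nPerSexPerCage = 50, seed = 23)
  fit <- fitWeibullCensored(dd, sex = "F")
  expect_equal(medianLifespan(fit), medianLifespan(start),
               tolerance = 1.5 / medianLifespan(start))
  expect_equal(fit@shape, 3, tolerance = 0.25)
})

test_that("degenerate death tables are rejected", {
  rec0 <- data.frame(cage_id = 1, sex = "M", day = 1, deaths = 0)
  dd0 <- dailyDeaths(rec0, initialN = 30, cages = 1)
  expect_error(fitWeibullCensored(dd0, "M"), "no events")
  rec1 <- data.frame(cage_id = 1, sex = "M", day = 5, deaths = 12)
  dd1 <- dailyDeaths(rec1, initialN = 30, cages = 1)
  expect_error(fitWeibullCensored(dd1, "M"), "distinct days")
})

test_that("daily-death tables and lifespan models round-trip through disk", {
  d <- defaultLifespans()
  dd <- genSurvivalExperiment(d, seed = 3)
  p <- tempfile(fileext = ".csv")
  writeDailyDeaths(dd, p)
  back <- readDailyDeaths(p)
  expect_equal(back@records$deaths, dd@records$deaths)
  expect_equal(back@initialN, dd@initialN)
  expect_equal(back@censorDay, dd@censorDay)
  pj <- tempfile(fileext = ".json")
  writeLifespanModel(d$male, pj)
  m2 <- readLifespanModel(pj)
  expect_equal(m2@shape, d$male@shape)
  expect_equal(m2@scale, d$male@scale)
  unlink(c(p, pj))
})
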