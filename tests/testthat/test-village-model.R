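test_that("competition survival composes exactly to the stated cumulative law", {
  expect_equal(competitionDailySurvival(0, 1000), 1)
  expect_equal(competitionDailySurvival(1000, 1000), 2^(-1 / 10))
  expect_equal(competitionDailySurvival(1000, 1000), 0.93303, tolerance = 1e-5)
  # 10-day composition law, exact algebra across magnitudes
  for (alpha in c(1, 350, 1e4)) for (JT in c(0, 10, 1e3, 1e7)) {
    expect_equal(competitionDailySurvival(JT, alpha)^10, alpha / (alpha + JT),
                 tolerance = 1e-12)
  }
  # cumulative death probability at J_T = alpha is one half
  expect_equal(1 - competitionDailySurvival(500, 500)^10, 0.5)
  expect_error(competitionDailySurvival(10, 0), "positive")
  expect_error(competitionDailySurvival(-1, 10), "non-negative")
})

test_that("alpha series follows the driver's linear rainfall form", {
  drv <- carryingCapacityDriver(waterCourseKm = 5, rainCoefficient = 2,
                                globalScale = 10)
  dry <- new("RainSeries", mm = rep(0, 52), frequency = "weekly")
  a <- alphaSeries(dry, drv, 300)
  expect_true(all(a == 10 * 5))            # dry-season floor c * L

  rain <- genRainfall(2, noiseCv = 0, seed = 1)
  a1 <- alphaSeries(rain, drv, 600)
  doubled <- new("RainSeries", mm = 2 * rainfallMm(rain),
                 frequency = "weekly")
  a2 <- alphaSeries(doubled, drv, 600)
  # doubling rainfall doubles the rain-dependent term exactly
  expect_equal(a2 - 10 * 5, 2 * (a1 - 10 * 5), tolerance = 1e-12)
  expect_true(all(a1 > 0))

  # alpha peaks within the trailing window of the rainfall peak
  dailyRain <- rep(rainfallMm(rain)[1:52], each = 7)
  expect_lte(abs(which.max(a1[1:364]) - which.max(dailyRain)), 14 + 7)

  expect_error(alphaSeries(rain, drv, 10000), "covers")
})

test_that("an empty village stays empty without releases", {
  cfg <- villageConfig()
  rain <- genRainfall(1, noiseCv = 0, seed = 1)
  # zero out the initial population via a day-1 cull of 100%
  s <- runVillage(cfg, rain, NULL, days = 120, seed = 1,
                  cull = list(day = 1, fraction = 1))
  d <- daily(s)
  expect_true(all(d$females == 0))
  expect_true(all(d$juveniles == 0))
  expect_true(all(d$males == 0))
})

test_that("release schedules share cumulative totals across intervals", {
  sizes <- vapply(c("weekly", "fortnightly", "monthly", "quarterly"),
                  function(iv) {
                    ev <- releaseEvents(makeSchedule(65000, iv))
                    sum(ev$males)
                  }, numeric(1))
  expect_true(all(sizes == 260000))
  wk <- releaseEvents(makeSchedule(65000, "weekly"))
  expect_equal(nrow(wk), 52)
  expect_true(all(wk$males == 5000))
  expect_true(all(diff(wk$day) == 7))
  fn <- releaseEvents(makeSchedule(65000, "fortnightly"))
  expect_true(all(fn$males == 10000))
  qt <- releaseEvents(makeSchedule(65000, "quarterly"))
  expect_equal(nrow(qt), 4)
  expect_true(all(qt$males == 65000))
  expect_equal(wk$day[1], 731)
})

test_that("transgenic males decay after releases stop", {
  cfg <- villageConfig(driver = carryingCapacityDriver(globalScale = 20))
  rain <- genRainfall(3, noiseCv = 0, seed = 2)
  # short pulse of releases early in year 2, then nothing
  sch <- new("ReleaseSchedule",
             events = data.frame(day = seq(400, 430, by = 7), males = 500),
             interval = "weekly")
  s <- suppressWarnings(runVillage(cfg, rain, sch, days = 900, seed = 3))
  d <- daily(s)
  peak <- max(d$transgenic_males[400:500])
  expect_gt(peak, 0)
  tailMean <- mean(d$transgenic_males[850:900])
  expect_lt(tailMean, 0.25 * peak)
})

test_that("density dependence compensates a one-off cull", {
  vf <- villageFixture()
  base <- daily(runVillage(vf$config, vf$rain, NULL, days = 500, seed = 9))
  culled <- daily(runVillage(vf$config, vf$rain, NULL, days = 500, seed = 9,
                             cull = list(day = 330, fraction = 0.5)))
  # halved at the cull ...
  expect_lt(culled$females[335] / base$females[335], 0.75)
  # ... but back within 10% of the unperturbed trajectory months later
  ratio <- mean(culled$females[450:500]) / mean(base$females[450:500])
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("calibration hits the target and scales monotonically", {
  vf <- villageFixture()
  expect_equal(vf$achieved, 35500, tolerance = 0.05)
  # doubling the calibrated scale increases the population roughly in
  # proportion (monotone, approximately linear compensation regime)
  d2 <- vf$config@driver; d2@globalScale <- 2 * d2@globalScale
  cfg2 <- vf$config; cfg2@driver <- d2
  f2 <- mean(vapply(100:102, function(s)
    daily(runVillage(cfg2, vf$rain, NULL, days = vf$measureDay,
                     seed = s))$females[vf$measureDay], numeric(1)))
  expect_gt(f2, 1.5 * vf$achieved)
  expect_lt(f2, 2.6 * vf$achieved)
  expect_error(calibrateAlpha(villageConfig(), vf$rain, targetFemales = 0),
               "positive")
})

test_that("village runs are reproducible and reductions respond to release size", {
  vf <- villageFixture()
  a <- daily(runVillage(vf$config, vf$rain, makeSchedule(65000, "weekly"),
                        years = 3, seed = 11))
  b <- daily(runVillage(vf$config, vf$rain, makeSchedule(65000, "weekly"),
                        years = 3, seed = 11))
  expect_identical(a, b)
  big <- daily(runVillage(vf$config, vf$rain, makeSchedule(650000, "weekly"),
                          years = 3, seed = 11))
  expect_lt(big$females[vf$measureDay], a$females[vf$measureDay])
})
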