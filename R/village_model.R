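#' @include AllClasses.R AllGenerics.R genetics.R
NULL

#' Construct a carrying-capacity driver
#'
#' @param waterCourseKm Water-course length (km), the dry-season floor.
#' @param rainCoefficient Weight of trailing mean rainfall.
#' @param trailingWindow Trailing-mean window, days.
#' @param globalScale Global scale c (calibrate with [calibrateAlpha()]).
#' @return A [CarryingCapacityDriver-class].
#' @export
carryingCapacityDriver <- function(waterCourseKm = 5, rainCoefficient = 2,
                                   trailingWindow = 14, globalScale = 300) {
  new("CarryingCapacityDriver", waterCourseKm = waterCourseKm,
      rainCoefficient = rainCoefficient, trailingWindow = trailingWindow,
      globalScale = globalScale)
}

#' Construct a village model configuration
#'
#' Defaults follow the field parameterisation: density-independent juvenile
#' mortality 0.05/day, 10-day development, Poisson(9) daily fecundity,
#' mark-release-recapture male daily survival 0.77 (range 0.69-0.87),
#' female daily survival 0.875, and a 2-year pre-release burn-in.
#'
#' @param maleDailySurvival Adult male daily survival probability.
#' @param femaleDailySurvival Adult female daily survival probability.
#' @param diJuvenileMortality Density-independent juvenile mortality/day.
#' @param developmentDays Days from oviposition to emergence.
#' @param eggsPerDay Poisson mean viable eggs per mated female per day.
#' @param maleBias Male probability under transgenic fathers.
#' @param driver A [CarryingCapacityDriver-class].
#' @param burnInDays Pre-release burn-in days (default 730).
#' @return A [VillageConfig-class].
#' @export
villageConfig <- function(maleDailySurvival = 0.77,
                          femaleDailySurvival = 0.875,
                          diJuvenileMortality = 0.05,
                          developmentDays = 10, eggsPerDay = 9,
                          maleBias = 0.95,
                          driver = carryingCapacityDriver(),
                          burnInDays = 730) {
  new("VillageConfig", diJuvenileMortality = diJuvenileMortality,
      developmentDays = developmentDays, eggsPerDay = eggsPerDay,
      maleBias = maleBias, maleDailySurvival = maleDailySurvival,
      femaleDailySurvival = femaleDailySurvival, driver = driver,
      burnInDays = burnInDays)
}

#' Daily survival from larval competition
#'
#' Competition over the 10-day development composes to a cumulative
#' survival \eqn{\alpha/(\alpha + J_T)}: \eqn{\alpha(t)} is the juvenile
#' count at which the probability of death from competition over the whole
#' of development is one half.  The per-day survival is therefore the
#' development-days-th root,
#' \deqn{s(J_T) = (\alpha/(\alpha + J_T))^{1/10}.}
#'
#' @param JT Total juveniles in the population (>= 0).
#' @param alpha Carrying-capacity parameter (> 0).
#' @param developmentDays Length of the juvenile stage (default 10).
#' @return Daily survival probability in (0, 1].
#' @examples
#' competitionDailySurvival(0, 1000)        # 1: no competition
#' competitionDailySurvival(1000, 1000)^10  # 0.5 cumulative survival
#' @export
competitionDailySurvival <- function(JT, alpha, developmentDays = 10) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  if (any(JT < 0)) stop("JT must be non-negative")
  (alpha / (alpha + JT))^(1 / developmentDays)
}

#' Daily carrying-capacity series from rainfall
#'
#' Expands weekly rainfall to daily values by repetition, forms the
#' trailing mean over the driver's window (partial windows at the start use
#' the available days), and applies the driver's linear form
#' \eqn{\alpha(t) = c (L + r \bar R_w(t))}.
#'
#' @param rainfall A [RainSeries-class].
#' @param driver A [CarryingCapacityDriver-class].
#' @param nDays Number of simulation days the series must cover.
#' @return Numeric vector of daily alpha values, length \code{nDays}.
#' @export
alphaSeries <- function(rainfall, driver, nDays) {
  mm <- rainfallMm(rainfall)
  dailyMm <- if (rainFrequency(rainfall) == "weekly")
    rep(mm, each = 7) else mm
  if (length(dailyMm) < nDays)
    stop("rainfall series covers ", length(dailyMm),
         " days but ", nDays, " are required")
  dailyMm <- dailyMm[seq_len(nDays)]
  # trailing mean over min(i, w) days ending at day i
  w <- as.integer(driver@trailingWindow)
  cs <- cumsum(dailyMm)
  idx <- seq_len(nDays)
  lower <- pmax(idx - w, 0)
  trail <- (cs - c(0, cs)[lower + 1]) / (idx - lower)
  driver@globalScale * (driver@waterCourseKm + driver@rainCoefficient * trail)
}

## ---- internal state ---------------------------------------------------

# Aggregated counts. Juveniles: slots 1..10 = emerges in that many days
# (array slot x genotype x sex). Adult males: counts by genotype (age is
# demographically inert under constant daily survival and is not tracked).
# Mated females: own genotype x mate genotype matrix. Unmated females: by
# genotype (mating happens same-day whenever males are present).
.newVillageState <- function(developmentDays, females0 = 1000,
                             males0 = 1000, juvPerSlot = 4500) {
  juv <- array(0, dim = c(developmentDays, 3, 2),
               dimnames = list(NULL, GENOTYPES, SEXES))
  juv[, "WT", "F"] <- round(juvPerSlot / 2)
  juv[, "WT", "M"] <- round(juvPerSlot / 2)
  mated <- matrix(0, 3, 3, dimnames = list(GENOTYPES, GENOTYPES))
  mated["WT", "WT"] <- females0
  list(juv = juv,
       males = c(WT = males0, HEMI = 0, HOMO = 0),
       mated = mated,
       unmated = c(WT = 0, HEMI = 0, HOMO = 0))
}

# One day. Order: juvenile thinning (DI + competition, start-of-day J_T);
# emergence + same-day mating; adult survival; releases; oviposition by
# females mated before today; bookkeeping.
.stepVillageDay <- function(state, alphaT, config, releaseToday) {
  dev <- config@developmentDays
  JT0 <- sum(state$juv)

  ## 1. juvenile survival
  if (JT0 > 0) {
    p <- (1 - config@diJuvenileMortality) *
      competitionDailySurvival(JT0, alphaT, dev)
    state$juv[] <- stats::rbinom(length(state$juv), state$juv, p)
  }

  ## 2. emergence (slot 1) and same-day mating
  emerging <- state$juv[1, , ]
  state$juv[seq_len(dev - 1), , ] <- state$juv[-1, , ]
  state$juv[dev, , ] <- 0
  state$males <- state$males + emerging[, "M"]
  toMate <- state$unmated + emerging[, "F"]
  newMated <- matrix(0, 3, 3, dimnames = list(GENOTYPES, GENOTYPES))
  totalMales <- sum(state$males)
  if (totalMales > 0) {
    for (gt in GENOTYPES) {
      if (toMate[[gt]] == 0) next
      newMated[gt, ] <- newMated[gt, ] +
        stats::rmultinom(1, toMate[[gt]], state$males)[, 1]
    }
    state$unmated[] <- 0
  } else {
    state$unmated <- toMate
  }

  ## 3. adult survival (males and mated females, incl. today's matings)
  state$males[] <- stats::rbinom(3, state$males, config@maleDailySurvival)
  state$mated[] <- stats::rbinom(9, state$mated, config@femaleDailySurvival)
  newMated[] <- stats::rbinom(9, newMated, config@femaleDailySurvival)

  ## 4. releases of zero-age hemizygous males
  if (releaseToday > 0)
    state$males[["HEMI"]] <- state$males[["HEMI"]] + releaseToday

  ## 5. oviposition by females mated before today
  for (mo in GENOTYPES) for (fa in GENOTYPES) {
    n <- state$mated[mo, fa]
    if (n == 0) next
    ne <- stats::rpois(1, config@eggsPerDay * n)
    if (ne == 0) next
    brood <- sampleBrood(ne, fa, mo, config@maleBias)
    state$juv[dev, , ] <- state$juv[dev, , ] + brood
  }
  state$mated <- state$mated + newMated
  state
}

#' Run the village population model
#'
#' Simulates the village population day by day: two burn-in years without
#' releases erase the arbitrary initial state, then the release schedule is
#' applied (by construction schedules start in year 3).  Deterministic for
#' a given seed.
#'
#' @param config A [VillageConfig-class].
#' @param rainfall A [RainSeries-class] covering the simulation span.
#' @param schedule A [ReleaseSchedule-class], or NULL for an unperturbed
#'   run.
#' @param years Simulated years (default 3: 2 burn-in + 1 release year).
#' @param seed Integer seed.
#' @param days Optional explicit number of days (overrides \code{years}).
#' @param cull Optional perturbation experiment: \code{list(day =, fraction =)}
#'   removes that fraction of every life stage (binomial thinning) at the
#'   start of the given day, e.g. to probe density-dependent compensation.
#' @return A [VillageSeries-class].
#' @export
runVillage <- function(config, rainfall, schedule = NULL, years = 3,
                       seed = 0, days = NULL, cull = NULL) {
  nDays <- if (is.null(days)) years * 365 else days
  alpha <- alphaSeries(rainfall, config@driver, nDays)
  rel <- numeric(nDays)
  if (!is.null(schedule)) {
    ev <- releaseEvents(schedule)
    ev <- ev[ev$day >= 1 & ev$day <= nDays, , drop = FALSE]
    if (nrow(ev)) {
      if (any(ev$day <= config@burnInDays))
        warning("release events scheduled during the burn-in are applied as given")
      rel[ev$day] <- rel[ev$day] + ev$males
    }
  }
  set.seed(seed)
  state <- .newVillageState(config@developmentDays)
  out <- matrix(0, nrow = nDays, ncol = 7)
  colnames(out) <- c("day", "females", "transgenic_females", "males",
                     "transgenic_males", "juveniles", "alpha")
  for (d in seq_len(nDays)) {
    if (!is.null(cull) && d == cull$day) {
      keepP <- 1 - cull$fraction
      state$juv[] <- stats::rbinom(length(state$juv), state$juv, keepP)
      state$males[] <- stats::rbinom(3, state$males, keepP)
      state$mated[] <- stats::rbinom(9, state$mated, keepP)
      state$unmated[] <- stats::rbinom(3, state$unmated, keepP)
    }
    state <- .stepVillageDay(state, alpha[d], config, rel[d])
    fem <- rowSums(state$mated) + state$unmated
    out[d, ] <- c(d, sum(fem), sum(fem[c("HEMI", "HOMO")]),
                  sum(state$males),
                  sum(state$males[c("HEMI", "HOMO")]),
                  sum(state$juv), alpha[d])
  }
  new("VillageSeries", daily = as.data.frame(out), config = config,
      seed = seed)
}

#' Build a release schedule with interval-independent cumulative totals
#'
#' Produces weekly, fortnightly, monthly (28-day) or quarterly (91-day)
#' release events over one 364-day release year starting at
#' \code{startDay}, sized so the cumulative total released is identical
#' across interval choices (any rounding remainder goes to the final
#' event).
#'
#' @param totalPerQuarter Cumulative males released per quarter.
#' @param interval One of \code{"weekly"}, \code{"fortnightly"},
#'   \code{"monthly"}, \code{"quarterly"}.
#' @param startDay First release day (default 731: first day of year 3).
#' @return A [ReleaseSchedule-class].
#' @examples
#' makeSchedule(65000, "weekly")       # 52 events of 5000
#' makeSchedule(65000, "quarterly")    # 4 events of 65000
#' @export
makeSchedule <- function(totalPerQuarter,
                         interval = c("weekly", "fortnightly", "monthly",
                                      "quarterly"),
                         startDay = 731) {
  interval <- match.arg(interval)
  step <- switch(interval, weekly = 7, fortnightly = 14, monthly = 28,
                 quarterly = 91)
  nEvents <- 364 %/% step
  annual <- 4 * totalPerQuarter
  per <- annual %/% nEvents
  males <- rep(per, nEvents)
  males[nEvents] <- males[nEvents] + annual - per * nEvents
  new("ReleaseSchedule",
      events = data.frame(day = startDay + step * (seq_len(nEvents) - 1),
                          males = males),
      interval = interval)
}

#' Calibrate the carrying-capacity scale to a target population size
#'
#' Bisection on log(c) until the mean unperturbed adult-female count at the
#' end of the rainy season (averaged over seeded replicates) is within
#' \code{tol} of the target.  The target corresponds to the study village's
#' unperturbed end-of-rainy-season population of about 35,500 females.
#'
#' @param config A [VillageConfig-class]; its driver's globalScale is the
#'   quantity being calibrated.
#' @param rainfall A [RainSeries-class] covering burn-in + release year.
#' @param targetFemales Target adult-female count (default 35500).
#' @param seasonEndDay Day-of-year of the end of the rainy season (default
#'   304, 31 October); measured in the first post-burn-in year.
#' @param replicates Seeded replicates per evaluation (default 5).
#' @param seed Base seed; replicate i uses \code{seed + i - 1}.
#' @param tol Relative tolerance on the achieved mean (default 0.05).
#' @param bracket Initial search interval for c.
#' @param maxIter Maximum bisection steps.
#' @return List: \code{config} (calibrated), \code{globalScale},
#'   \code{achieved} (mean females at the measurement day),
#'   \code{measureDay}.
#' @export
calibrateAlpha <- function(config, rainfall, targetFemales = 35500,
                           seasonEndDay = 304, replicates = 5, seed = 0,
                           tol = 0.05, bracket = c(1, 1e5), maxIter = 40) {
  if (targetFemales <= 0) stop("targetFemales must be positive")
  measureDay <- config@burnInDays + seasonEndDay
  evalC <- function(cc) {
    d <- config@driver; d@globalScale <- cc
    cfg <- config; cfg@driver <- d
    mean(vapply(seq_len(replicates), function(i) {
      s <- runVillage(cfg, rainfall, NULL, seed = seed + i - 1,
                      days = measureDay)
      daily(s)$females[measureDay]
    }, numeric(1)))
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- evalC(lo); fhi <- evalC(hi)
  if (flo > targetFemales || fhi < targetFemales)
    stop(sprintf(paste0("calibration bracket does not straddle the target: ",
                        "f(%g) = %.0f, f(%g) = %.0f, target %g"),
                 lo, flo, hi, fhi, targetFemales))
  achieved <- NA_real_; cc <- NA_real_
  for (it in seq_len(maxIter)) {
    cc <- exp((log(lo) + log(hi)) / 2)
    achieved <- evalC(cc)
    if (abs(achieved - targetFemales) / targetFemales < tol) break
    if (achieved < targetFemales) lo <- cc else hi <- cc
  }
  d <- config@driver; d@globalScale <- cc
  config@driver <- d
  list(config = config, globalScale = cc, achieved = achieved,
       measureDay = measureDay)
}
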