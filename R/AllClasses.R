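#' @import methods
NULL

#' Transgene genotype codes
#'
#' The transgene is an autosomal dominant-marker construct; an individual is
#' wild type (\code{"WT"}), hemizygous (\code{"HEMI"}) or homozygous
#' (\code{"HOMO"}).  All package functions exchange genotypes as these
#' three-letter strings.
#'
#' @format Character vector of length 3.
#' @export
GENOTYPES <- c("WT", "HEMI", "HOMO")

#' Sex codes used throughout the package
#' @format Character vector \code{c("F", "M")}.
#' @export
SEXES <- c("F", "M")

#' Offspring genotype distribution for one mating pair
#'
#' Holds the Mendelian genotype probabilities of a brood together with the
#' probability that any one egg is male.  The male probability depends only
#' on the father: transgenic (hemi- or homozygous) fathers sire a strongly
#' male-biased brood (0.95 by default), wild-type fathers an unbiased one.
#'
#' @slot probs Named numeric vector over \code{GENOTYPES}; sums to 1.
#' @slot maleProb Probability that an egg is male.
#' @seealso [offspringDistribution()], [sampleBrood()]
#' @export
setClass("CrossDistribution",
  representation(probs = "numeric", maleProb = "numeric"))

setValidity("CrossDistribution", function(object) {
  p <- object@probs
  if (!identical(names(p), GENOTYPES))
    return("probs must be named WT, HEMI, HOMO (in that order)")
  if (any(p < 0) || any(p > 1)) return("genotype probabilities outside [0,1]")
  if (abs(sum(p) - 1) > 1e-12) return("genotype probabilities must sum to 1")
  if (length(object@maleProb) != 1 ||
      object@maleProb < 0 || object@maleProb > 1)
    return("maleProb must be a single probability")
  TRUE
})

#' Weibull adult-lifespan model
#'
#' Adult lifespans in the cage model are Weibull distributed with sex-specific
#' shape and scale.  The median is \code{scale * log(2)^(1/shape)}.
#'
#' @slot shape Dimensionless Weibull shape (> 0).
#' @slot scale Weibull scale in days (> 0).
#' @slot sex Either \code{"male"} or \code{"female"} (label only).
#' @seealso [defaultLifespans()], [fitWeibullCensored()], [sampleLifespan()]
#' @export
setClass("LifespanModel",
  representation(shape = "numeric", scale = "numeric", sex = "character"))

setValidity("LifespanModel", function(object) {
  if (length(object@shape) != 1 || !is.finite(object@shape) ||
      object@shape <= 0) return("shape must be a single positive number")
  if (length(object@scale) != 1 || !is.finite(object@scale) ||
      object@scale <= 0) return("scale must be a single positive number")
  if (!object@sex %in% c("male", "female"))
    return("sex must be 'male' or 'female'")
  TRUE
})

#' Daily death counts from an adult survival experiment
#'
#' Cages of adults are checked daily; deaths are counted and removed until a
#' censoring day, after which remaining survivors are counted once.  This is
#' the input for interval/right-censored Weibull fitting.
#'
#' @slot records data.frame with columns \code{cage_id}, \code{sex}
#'   (\code{"M"}/\code{"F"}), \code{day} (1-based), \code{deaths}.
#' @slot initialN Individuals per cage per sex at day 0.
#' @slot cages Number of cages.
#' @slot censorDay Day at which survivors are right-censored (default 42).
#' @export
setClass("DailyDeaths",
  representation(records = "data.frame", initialN = "numeric",
                 cages = "numeric", censorDay = "numeric"))

setValidity("DailyDeaths", function(object) {
  r <- object@records
  need <- c("cage_id", "sex", "day", "deaths")
  if (!all(need %in% names(r)))
    return("records needs columns cage_id, sex, day, deaths")
  if (any(r$deaths < 0)) return("negative death counts")
  if (any(r$day < 1 | r$day > object@censorDay))
    return("death days must lie in 1..censorDay")
  # per cage x sex, deaths cannot exceed the starting number
  if (nrow(r) > 0) {
    tot <- stats::aggregate(deaths ~ cage_id + sex, data = r, FUN = sum)
    if (any(tot$deaths > object@initialN))
      return("more deaths than initial individuals in some cage/sex")
  }
  TRUE
})

#' Cage trial protocol
#'
#' Complete dated event schedule for one large-cage trial: target-population
#' establishment additions, twice-weekly transgenic-male releases, the
#' twice-weekly oviposition/restocking cadence, and the demographic
#' parameters shared with the village model.
#'
#' Day 0 is a Monday.  Oviposition (egg collection + restock sampling)
#' happens on Mondays and Thursdays; adult additions and releases on
#' Tuesdays and Fridays.
#'
#' @slot trialStyle \code{"trial1"} or \code{"trial23"}.
#' @slot treatment \code{"control"}, \code{"ratio_1_1"} or \code{"ratio_3_1"}.
#' @slot establishment data.frame(day, females, males, stationary) of adult
#'   additions; \code{stationary} marks the trial-1 day-0 seed population
#'   whose ages follow the stable-age residual-lifetime distribution.
#' @slot releaseSize Transgenic males per release event (0 for control).
#' @slot releaseStart First day on/after which Tue/Fri releases occur.
#' @slot durationDays Total simulated days.
#' @slot restockSampleSize Eggs kept per oviposition day (default 100).
#' @slot developmentDays Days from oviposition to adult emergence (10).
#' @slot eggsPerDay Poisson mean of viable eggs per female per permitted day.
#' @slot maleBias P(male egg) when the father is transgenic.
#' @slot maleLifespan,femaleLifespan [LifespanModel-class] objects.
#' @seealso [buildProtocol()], [runCage()]
#' @export
setClass("CageProtocol",
  representation(trialStyle = "character", treatment = "character",
    establishment = "data.frame", releaseSize = "numeric",
    releaseStart = "numeric", durationDays = "numeric",
    restockSampleSize = "numeric", developmentDays = "numeric",
    eggsPerDay = "numeric", maleBias = "numeric",
    maleLifespan = "LifespanModel", femaleLifespan = "LifespanModel"))

setValidity("CageProtocol", function(object) {
  if (!object@treatment %in% c("control", "ratio_1_1", "ratio_3_1"))
    return("unknown treatment")
  if (!object@trialStyle %in% c("trial1", "trial23"))
    return("unknown trial style")
  if (!object@releaseSize %in% c(0, 50, 150))
    return("releaseSize must be 0, 50 or 150 under the default protocols")
  if (object@restockSampleSize <= 0) return("restockSampleSize must be > 0")
  if (object@developmentDays < 1) return("developmentDays must be >= 1")
  TRUE
})

#' Observable time series from one cage run
#'
#' @slot samples data.frame, one row per oviposition (collection) day:
#'   \code{day}, \code{eggs_laid}, restocked counts by genotype and sex,
#'   \code{restock_female}, \code{restock_male}, \code{restock_transgenic},
#'   \code{prop_female}, \code{transgene_freq}.
#' @slot census data.frame, one row per day: adult male/female counts and
#'   the count of transgenic adults.
#' @slot protocol The [CageProtocol-class] that generated the run.
#' @slot seed Integer seed of the run.
#' @export
setClass("CageSeries",
  representation(samples = "data.frame", census = "data.frame",
                 protocol = "CageProtocol", seed = "numeric"))

setValidity("CageSeries", function(object) {
  s <- object@samples
  pf <- s$prop_female[!is.na(s$prop_female)]
  tf <- s$transgene_freq[!is.na(s$transgene_freq)]
  if (length(pf) && (any(pf < 0) || any(pf > 1)))
    return("prop_female outside [0,1]")
  if (length(tf) && (any(tf < 0) || any(tf > 1)))
    return("transgene_freq outside [0,1]")
  TRUE
})

#' Rainfall series
#'
#' Weekly (or daily) rainfall depths driving the village carrying capacity.
#'
#' @slot mm Non-negative rainfall depths.
#' @slot frequency \code{"weekly"} or \code{"daily"}.
#' @seealso [genRainfall()], [alphaSeries()]
#' @export
setClass("RainSeries",
  representation(mm = "numeric", frequency = "character"))

setValidity("RainSeries", function(object) {
  if (any(!is.finite(object@mm)) || any(object@mm < 0))
    return("rainfall must be finite and non-negative")
  if (!object@frequency %in% c("weekly", "daily"))
    return("frequency must be 'weekly' or 'daily'")
  TRUE
})

#' Rainfall-driven carrying-capacity driver
#'
#' Supplies the time-varying competition parameter \eqn{\alpha(t)}: the
#' juvenile count at which cumulative larval-competition mortality over
#' development is one half.  The default functional form is linear in the
#' trailing mean rainfall with a dry-season floor set by the length of
#' permanent water courses:
#' \deqn{\alpha(t) = c\,(L + r\,\bar{R}_{w}(t))}
#' where \eqn{\bar{R}_w(t)} is the mean rainfall over the trailing
#' \code{trailingWindow} days, \eqn{L} the water-course length and \eqn{c}
#' a global scale fixed by calibration to a target population size.
#'
#' @slot waterCourseKm Water-course length L (km); dry-season floor.
#' @slot rainCoefficient Weight r of trailing rainfall (km per mm).
#' @slot trailingWindow Trailing-mean window in days (default 14).
#' @slot globalScale Global scale c, set by [calibrateAlpha()].
#' @export
setClass("CarryingCapacityDriver",
  representation(waterCourseKm = "numeric", rainCoefficient = "numeric",
                 trailingWindow = "numeric", globalScale = "numeric"))

setValidity("CarryingCapacityDriver", function(object) {
  if (object@waterCourseKm <= 0) return("waterCourseKm must be > 0")
  if (object@rainCoefficient < 0) return("rainCoefficient must be >= 0")
  if (object@trailingWindow < 1) return("trailingWindow must be >= 1 day")
  if (object@globalScale <= 0) return("globalScale must be > 0")
  TRUE
})

#' Village model configuration
#'
#' Daily-step demography of a single village population with
#' rainfall-driven density-dependent larval competition, constant adult
#' daily survival, and a two-year burn-in before any releases.
#'
#' @slot diJuvenileMortality Density-independent juvenile death probability
#'   per day (default 0.05).
#' @slot developmentDays Days from oviposition to emergence (10).
#' @slot eggsPerDay Poisson mean of viable eggs per mated female per day (9).
#' @slot maleBias P(male egg) for transgenic fathers (0.95).
#' @slot maleDailySurvival Adult male daily survival; field estimates span
#'   0.69--0.87 with mean 0.77.
#' @slot femaleDailySurvival Adult (mated) female daily survival (0.875).
#' @slot driver [CarryingCapacityDriver-class].
#' @slot burnInDays Pre-release burn-in (730 days).
#' @seealso [villageConfig()], [runVillage()], [calibrateAlpha()]
#' @export
setClass("VillageConfig",
  representation(diJuvenileMortality = "numeric", developmentDays = "numeric",
    eggsPerDay = "numeric", maleBias = "numeric",
    maleDailySurvival = "numeric", femaleDailySurvival = "numeric",
    driver = "CarryingCapacityDriver", burnInDays = "numeric"))

setValidity("VillageConfig", function(object) {
  pr <- c(object@diJuvenileMortality, object@maleDailySurvival,
          object@femaleDailySurvival, object@maleBias)
  if (any(pr <= 0) || any(pr >= 1))
    return("all probabilities must lie strictly in (0,1)")
  if (object@developmentDays < 1) return("developmentDays must be >= 1")
  if (object@eggsPerDay <= 0) return("eggsPerDay must be > 0")
  TRUE
})

#' Release schedule for the village model
#'
#' @slot events data.frame(day, males): hemizygous-male release events in
#'   absolute simulation days.
#' @slot interval One of weekly, fortnightly, monthly, quarterly.
#' @seealso [makeSchedule()]
#' @export
setClass("ReleaseSchedule",
  representation(events = "data.frame", interval = "character"))

setValidity("ReleaseSchedule", function(object) {
  if (!all(c("day", "males") %in% names(object@events)))
    return("events needs columns day, males")
  if (any(object@events$males < 0)) return("negative release sizes")
  TRUE
})

#' Daily output of one village run
#'
#' @slot daily data.frame, one row per day: \code{day}, \code{females}
#'   (adult females), \code{transgenic_females}, \code{males},
#'   \code{transgenic_males}, \code{juveniles} (J_T), \code{alpha}.
#' @slot config The [VillageConfig-class] used.
#' @slot seed Integer seed of the run.
#' @export
setClass("VillageSeries",
  representation(daily = "data.frame", config = "VillageConfig",
                 seed = "numeric"))

setValidity("VillageSeries", function(object) {
  d <- object@daily
  if (any(d$females < 0) || any(d$juveniles < 0))
    return("negative population counts")
  TRUE
})

#' Pointwise percentile envelope over replicate simulations
#'
#' For each observable and time point: the mean and the empirical
#' 2.5th/97.5th percentiles (order statistics) across replicates, emulating
#' the 95% band of an ensemble of model simulations.
#'
#' @slot days Time points (collection days).
#' @slot mean,lower,upper Matrices (day x variable).
#' @slot replicates Named list of day x replicate matrices, one per variable.
#' @slot nReplicates Number of replicate runs.
#' @slot probs Envelope probabilities, default c(0.025, 0.975).
#' @seealso [ensemble()], [envelopeCoverage()], [post45Summary()]
#' @export
setClass("EnsembleSummary",
  representation(days = "numeric", mean = "matrix", lower = "matrix",
                 upper = "matrix", replicates = "list",
                 nReplicates = "numeric", probs = "numeric"))

setValidity("EnsembleSummary", function(object) {
  ok <- object@lower <= object@mean + 1e-12 &
        object@mean <= object@upper + 1e-12
  if (!all(ok | is.na(ok))) return("need lower <= mean <= upper pointwise")
  if (object@nReplicates < 2) return("an ensemble needs >= 2 replicates")
  TRUE
})

#' Observation-noise-corrupted cage observables
#'
#' Emulates the experimental measurement design: per collection day, a total
#' egg count, a hatch sample of ~200 eggs, and a screened offspring sample
#' of ~100 individuals scored for sex and the fluorescent transgene marker.
#'
#' @slot observations data.frame(day, eggs, hatch_n, hatched, screen_n,
#'   females, transgenics).
#' @seealso [genObservedSeries()]
#' @export
setClass("ObservedSeries", representation(observations = "data.frame"))

setValidity("ObservedSeries", function(object) {
  o <- object@observations
  if (any(o$hatched > o$hatch_n) || any(o$females > o$screen_n) ||
      any(o$transgenics > o$screen_n))
    return("sample successes exceed sample sizes")
  TRUE
})
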