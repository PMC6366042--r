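#' @include AllClasses.R AllGenerics.R lifehistory.R
NULL

#' Generate a synthetic adult survival experiment
#'
#' Emulates the 12-cage design: each cage starts with 30 males and 30
#' females whose lifespans are Weibull draws from the supplied models;
#' deaths are tallied daily and the experiment is right-censored at 42
#' days.
#'
#' @param models List with \code{male} and \code{female}
#'   [LifespanModel-class] objects.
#' @param cages Number of cages (default 12).
#' @param nPerSexPerCage Individuals per sex per cage (default 30).
#' @param censorDay Censoring day (default 42).
#' @param seed Integer seed.
#' @return A [DailyDeaths-class].
#' @export
genSurvivalExperiment <- function(models, cages = 12, nPerSexPerCage = 30,
                                  censorDay = 42, seed = 0) {
  set.seed(seed)
  rows <- list()
  for (cage in seq_len(cages)) {
    for (sx in c("M", "F")) {
      model <- if (sx == "M") models$male else models$female
      dd <- ceiling(sampleLifespan(nPerSexPerCage, model))
      dd <- dd[dd <= censorDay]                 # the rest are censored
      if (length(dd)) {
        tab <- table(dd)
        rows[[length(rows) + 1L]] <- data.frame(
          cage_id = cage, sex = sx, day = as.integer(names(tab)),
          deaths = as.integer(tab))
      }
    }
  }
  rec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cage_id = integer(0), sex = character(0),
               day = integer(0), deaths = integer(0))
  dailyDeaths(rec, initialN = nPerSexPerCage, cages = cages,
              censorDay = censorDay)
}

#' Generate synthetic Sahelian rainfall
#'
#' Weekly rainfall with a unimodal (wrapped-Gaussian) wet season peaking in
#' early August, a small dry-season floor, and mean-preserving
#' multiplicative lognormal noise.  A stand-in for reanalysis rainfall over
#' a Burkina Faso village: the July-September wet season carries an order
#' of magnitude more rain than December-February.
#'
#' @param years Number of years (52 weeks each).
#' @param peakDay Day-of-year of the seasonal peak (default 213, ~1 Aug).
#' @param peakMm Peak weekly rainfall (mm).
#' @param dryMm Dry-season weekly floor (mm).
#' @param widthDays Gaussian width of the wet season (days).
#' @param noiseCv Coefficient of variation of the multiplicative noise
#'   (0 for a deterministic, exactly periodic series).
#' @param seed Integer seed.
#' @return A weekly [RainSeries-class] of length \code{52 * years}.
#' @export
genRainfall <- function(years, peakDay = 213, peakMm = 60, dryMm = 1,
                        widthDays = 60, noiseCv = 0.3, seed = 0) {
  if (years < 1) stop("years must be >= 1")
  set.seed(seed)
  weeks <- seq_len(52 * years)
  mid <- (weeks - 1) * 7 + 3.5           # week midpoint in days
  doy <- mid %% 364                      # 52-week year
  d <- ((doy - peakDay + 182) %% 364) - 182
  profile <- dryMm + (peakMm - dryMm) * exp(-d^2 / (2 * widthDays^2))
  if (noiseCv > 0) {
    sdlog <- sqrt(log(1 + noiseCv^2))
    profile <- profile * stats::rlnorm(length(profile), -sdlog^2 / 2, sdlog)
  }
  new("RainSeries", mm = pmax(profile, 0), frequency = "weekly")
}

#' Corrupt a simulated cage series with observation noise
#'
#' Applies the experimental measurement design to a model-generated truth:
#' per collection day, a hatch sample of about 200 eggs and a screened
#' offspring sample of about 100 individuals, with binomial counting noise
#' (unbiased for the underlying proportions).  A beta-binomial
#' overdispersion hook (\code{rho}) is provided for emulating noisier field
#' sampling such as ovitrap data.
#'
#' @param trueSeries A [CageSeries-class].
#' @param seed Integer seed.
#' @param hatchN Hatch sample size (default 200).
#' @param screenN Offspring screen size (default 100).
#' @param hatchRate True hatch probability (not a model output; default
#'   0.87).
#' @param rho Beta-binomial intra-class correlation; 0 (default) gives
#'   plain binomial noise.
#' @return An [ObservedSeries-class].
#' @export
genObservedSeries <- function(trueSeries, seed = 0, hatchN = 200,
                              screenN = 100, hatchRate = 0.87, rho = 0) {
  set.seed(seed)
  s <- samples(trueSeries)
  rbin <- function(n, size, prob) {
    prob <- rep_len(prob, n)
    ok <- !is.na(prob)
    out <- rep(NA_integer_, n)
    if (rho > 0) {
      a <- prob * (1 - rho) / rho
      b <- (1 - prob) * (1 - rho) / rho
      p2 <- ifelse(ok & prob > 0 & prob < 1,
                   stats::rbeta(n, pmax(a, 1e-12), pmax(b, 1e-12)), prob)
    } else p2 <- prob
    out[ok] <- stats::rbinom(sum(ok), size[ok], p2[ok])
    out
  }
  nr <- nrow(s)
  hn <- pmin(hatchN, s$eggs_laid)
  sn <- ifelse(s$restock_total > 0, pmin(screenN, s$restock_total), 0L)
  obs <- data.frame(
    day = s$day, eggs = s$eggs_laid,
    hatch_n = hn,
    hatched = rbin(nr, hn, rep(hatchRate, nr)),
    screen_n = sn,
    females = rbin(nr, sn, s$prop_female),
    transgenics = rbin(nr, sn, s$transgene_freq))
  obs$hatched[hn == 0] <- 0L
  obs$females[sn == 0] <- 0L
  obs$transgenics[sn == 0] <- 0L
  new("ObservedSeries", observations = obs)
}
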