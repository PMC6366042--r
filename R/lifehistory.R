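#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a Weibull lifespan model
#'
#' @param shape,scale Weibull parameters (shape dimensionless, scale days).
#' @param sex \code{"male"} or \code{"female"} (label only).
#' @return A [LifespanModel-class].
#' @export
lifespanModel <- function(shape, scale, sex = "female") {
  new("LifespanModel", shape = shape, scale = scale, sex = sex)
}

#' Weibull survival function
#'
#' \eqn{S(t) = \exp(-(t/\mathrm{scale})^\mathrm{shape})}.
#'
#' @param t Age in days (>= 0); vectorised.
#' @param model A [LifespanModel-class].
#' @return Survival probabilities in (0, 1].
#' @export
weibullSurvival <- function(t, model) {
  if (any(t < 0)) stop("t must be non-negative")
  exp(-(t / model@scale)^model@shape)
}

#' Default adult lifespan models
#'
#' Sex-specific Weibull lifespans reproducing the survival experiment's
#' median longevities of 28 days (males) and 30 days (females).  The shape
#' (default 4) is set so that only a few percent of adults survive to the
#' 42-day censoring horizon (about 3% of males and 7% of females), matching
#' the observation that almost all adults were dead by then.  The scale is
#' the closed-form inversion \code{median / log(2)^(1/shape)}.
#'
#' @param shape Common Weibull shape.
#' @param maleMedian,femaleMedian Median longevities in days.
#' @return List with elements \code{male} and \code{female}.
#' @examples
#' m <- defaultLifespans()
#' medianLifespan(m$male)    # 28
#' weibullSurvival(42, m$female)
#' @export
defaultLifespans <- function(shape = 4, maleMedian = 28, femaleMedian = 30) {
  mk <- function(med, sex)
    lifespanModel(shape = shape, scale = med / log(2)^(1 / shape), sex = sex)
  list(male = mk(maleMedian, "male"), female = mk(femaleMedian, "female"))
}

#' Draw random lifespans
#'
#' @param n Number of draws.
#' @param model A [LifespanModel-class].
#' @return Continuous lifespans in days (uses the session RNG; seed the run
#'   with \code{set.seed} for reproducibility).
#' @export
sampleLifespan <- function(n, model) {
  stats::rweibull(n, shape = model@shape, scale = model@scale)
}

# Residual-lifetime draws under the stationary (stable-age) population:
# density S(t)/mu. Used to seed trial 1's pre-existing target population.
# Numeric inverse CDF on a fine grid; upper limit where S is negligible.
.sampleResidualLifespan <- function(n, model) {
  tmax <- model@scale * (-log(1e-12))^(1 / model@shape)
  grid <- seq(0, tmax, length.out = 4096)
  s <- weibullSurvival(grid, model)
  cdf <- cumsum(s)
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, grid, xout = stats::runif(n), ties = "ordered",
                yleft = 0, yright = tmax)$y
}

#' Assemble a daily-deaths object
#'
#' @param records data.frame with columns cage_id, sex, day, deaths.
#' @param initialN Starting individuals per cage per sex.
#' @param cages Number of cages (default: distinct cage ids in records).
#' @param censorDay Right-censoring day (default 42).
#' @return A [DailyDeaths-class].
#' @export
dailyDeaths <- function(records, initialN,
                        cages = length(unique(records$cage_id)),
                        censorDay = 42) {
  records <- records[records$deaths > 0, , drop = FALSE]
  new("DailyDeaths", records = records, initialN = initialN,
      cages = cages, censorDay = censorDay)
}

#' Fit a Weibull lifespan model to censored daily death counts
#'
#' Maximum-likelihood Weibull fit treating a death recorded on day d as
#' interval-censored on (d-1, d] (the experiment only records daily counts)
#' and survivors at the censoring day as right-censored.  The likelihood is
#' maximised by \code{survival::survreg}; the location/scale estimates are
#' converted back to Weibull shape and scale.
#'
#' @param data A [DailyDeaths-class].
#' @param sex Which sex to fit (\code{"M"} or \code{"F"}); records of the
#'   other sex are ignored.  Fits are per sex because male and female
#'   survival differ significantly in the source experiment.
#' @return A [LifespanModel-class] carrying the fitted parameters.
#' @examples
#' mods <- defaultLifespans()
#' dd <- genSurvivalExperiment(mods, seed = 1)
#' fitWeibullCensored(dd, sex = "M")
#' @export
fitWeibullCensored <- function(data, sex = c("M", "F")) {
  sex <- match.arg(sex)
  stopifnot(is(data, "DailyDeaths"))
  rec <- data@records
  rec <- rec[rec$sex == sex & rec$deaths > 0, , drop = FALSE]
  nEvents <- sum(rec$deaths)
  if (nEvents == 0) stop("no events")
  if (length(unique(rec$day)) < 2)
    stop("need deaths on at least 2 distinct days to identify the shape")
  nTotal <- data@cages * data@initialN
  nCens <- nTotal - nEvents
  # interval-censored events: (d-1, d]; left endpoint 0 coded as tiny > 0
  t1 <- pmax(rec$day - 1, 1e-8)
  t2 <- rec$day
  w <- rec$deaths
  if (nCens > 0) {
    t1 <- c(t1, data@censorDay)
    t2 <- c(t2, NA)           # NA upper bound = right-censored (interval2)
    w <- c(w, nCens)
  }
  fit <- survival::survreg(survival::Surv(t1, t2, type = "interval2") ~ 1,
                           weights = w, dist = "weibull")
  shape <- 1 / fit$scale
  scale <- exp(unname(stats::coef(fit)[1]))
  lifespanModel(shape = shape, scale = scale,
                sex = if (sex == "M") "male" else "female")
}
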