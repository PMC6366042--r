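#' @include AllClasses.R
NULL

#' Accessors for pmbpop objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x A pmbpop S4 object.
#' @param ... Passed to methods.
#' @return The requested component (vector, data.frame or number).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("crossProbs", function(x) standardGeneric("crossProbs"))
#' @rdname accessors
#' @export
setGeneric("maleProb", function(x) standardGeneric("maleProb"))
#' @rdname accessors
#' @export
setGeneric("medianLifespan", function(x) standardGeneric("medianLifespan"))
#' @rdname accessors
#' @export
setGeneric("samples", function(x, ...) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("census", function(x, ...) standardGeneric("census"))
#' @rdname accessors
#' @export
setGeneric("daily", function(x, ...) standardGeneric("daily"))
#' @rdname accessors
#' @export
setGeneric("observations", function(x, ...) standardGeneric("observations"))
#' @rdname accessors
#' @export
setGeneric("releaseEvents", function(x) standardGeneric("releaseEvents"))
#' @rdname accessors
#' @export
setGeneric("rainfallMm", function(x) standardGeneric("rainfallMm"))
#' @rdname accessors
#' @export
setGeneric("rainFrequency", function(x) standardGeneric("rainFrequency"))
#' @rdname accessors
#' @export
setGeneric("envelopeBand", function(x, variable) standardGeneric("envelopeBand"))

#' Run an ensemble of seeded simulations
#'
#' @param x A protocol or configuration object.
#' @param n Number of replicate runs.
#' @param baseSeed Seed of the first replicate; replicate i uses
#'   \code{baseSeed + i - 1}.
#' @param ... Method-specific arguments.
#' @return An [EnsembleSummary-class].
#' @export
setGeneric("ensemble", function(x, n = 100, baseSeed = 0, ...)
  standardGeneric("ensemble"))

#' Post-threshold summary of cage observables
#'
#' Mean and standard error of the proportion female and the transgene
#' frequency over collection days after a threshold day (default 45),
#' matching the experimental six-weeks-in summary window.
#'
#' @param x A [CageSeries-class] or [EnsembleSummary-class].
#' @param threshold Collection days strictly greater than this enter the
#'   summary (default 45).
#' @return A data.frame with one row per variable: mean, se, n_days.
#' @export
setGeneric("post45Summary", function(x, threshold = 45)
  standardGeneric("post45Summary"))

## ---- accessor methods -------------------------------------------------

#' @rdname accessors
#' @export
setMethod("crossProbs", "CrossDistribution", function(x) x@probs)
#' @rdname accessors
#' @export
setMethod("maleProb", "CrossDistribution", function(x) x@maleProb)
#' @rdname accessors
#' @export
setMethod("medianLifespan", "LifespanModel",
  function(x) x@scale * log(2)^(1 / x@shape))
#' @rdname accessors
#' @export
setMethod("samples", "CageSeries", function(x, ...) x@samples)
#' @rdname accessors
#' @export
setMethod("census", "CageSeries", function(x, ...) x@census)
#' @rdname accessors
#' @export
setMethod("daily", "VillageSeries", function(x, ...) x@daily)
#' @rdname accessors
#' @export
setMethod("observations", "ObservedSeries", function(x, ...) x@observations)
#' @rdname accessors
#' @export
setMethod("releaseEvents", "ReleaseSchedule", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("rainfallMm", "RainSeries", function(x) x@mm)
#' @rdname accessors
#' @export
setMethod("rainFrequency", "RainSeries", function(x) x@frequency)

#' @rdname accessors
#' @param variable Variable name, e.g. \code{"prop_female"}.
#' @export
setMethod("envelopeBand", "EnsembleSummary", function(x, variable) {
  if (!variable %in% colnames(x@mean))
    stop("unknown ensemble variable: ", variable)
  data.frame(day = x@days, mean = x@mean[, variable],
             lower = x@lower[, variable], upper = x@upper[, variable])
})

## ---- show methods -----------------------------------------------------

setMethod("show", "LifespanModel", function(object) {
  cat(sprintf("LifespanModel (%s): Weibull shape %.3f, scale %.2f d, median %.2f d\n",
              object@sex, object@shape, object@scale,
              medianLifespan(object)))
})

setMethod("show", "CrossDistribution", function(object) {
  cat("CrossDistribution  P(male) =", format(object@maleProb), "\n")
  print(round(object@probs, 4))
})

setMethod("show", "CageProtocol", function(object) {
  cat(sprintf("CageProtocol %s / %s\n", object@trialStyle, object@treatment))
  cat(sprintf("  establishment additions: %d; release size %d (Tue/Fri from day %d)\n",
              nrow(object@establishment), object@releaseSize,
              object@releaseStart))
  cat(sprintf("  duration %d d; restock %d eggs; development %d d\n",
              object@durationDays, object@restockSampleSize,
              object@developmentDays))
})

setMethod("show", "CageSeries", function(object) {
  cat(sprintf("CageSeries (%s/%s, seed %d): %d collection days over %d days\n",
              object@protocol@trialStyle, object@protocol@treatment,
              as.integer(object@seed), nrow(object@samples),
              object@protocol@durationDays))
})

setMethod("show", "VillageConfig", function(object) {
  cat(sprintf("VillageConfig: male surv %.3f/d, female surv %.3f/d, DI juvenile mort %.2f/d\n",
              object@maleDailySurvival, object@femaleDailySurvival,
              object@diJuvenileMortality))
  d <- object@driver
  cat(sprintf("  alpha(t) = %.4g * (%.4g + %.4g * trailing %d-day mean rain); burn-in %d d\n",
              d@globalScale, d@waterCourseKm, d@rainCoefficient,
              as.integer(d@trailingWindow), as.integer(object@burnInDays)))
})

setMethod("show", "VillageSeries", function(object) {
  d <- object@daily
  cat(sprintf("VillageSeries (seed %d): %d days; final adult females %d\n",
              as.integer(object@seed), nrow(d), as.integer(d$females[nrow(d)])))
})

setMethod("show", "ReleaseSchedule", function(object) {
  e <- object@events
  cat(sprintf("ReleaseSchedule (%s): %d events, %s males total\n",
              object@interval, nrow(e), format(sum(e$males))))
})

setMethod("show", "EnsembleSummary", function(object) {
  cat(sprintf("EnsembleSummary: %d replicates, %d time points, variables: %s\n",
              as.integer(object@nReplicates), length(object@days),
              paste(colnames(object@mean), collapse = ", ")))
})

setMethod("show", "RainSeries", function(object) {
  cat(sprintf("RainSeries (%s): %d values, mean %.2f mm\n",
              object@frequency, length(object@mm), mean(object@mm)))
})

setMethod("show", "DailyDeaths", function(object) {
  r <- object@records
  cat(sprintf("DailyDeaths: %d cages x %d per sex, censored at day %d, %d deaths recorded\n",
              as.integer(object@cages), as.integer(object@initialN),
              as.integer(object@censorDay), as.integer(sum(r$deaths))))
})

setMethod("show", "ObservedSeries", function(object) {
  cat(sprintf("ObservedSeries: %d collection days\n",
              nrow(object@observations)))
})
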