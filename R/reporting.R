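#' @include AllClasses.R AllGenerics.R cage_model.R
NULL

#' Build an ensemble summary from replicate matrices
#'
#' Pointwise mean and empirical percentile band (order statistics,
#' \code{quantile type = 1}, hence equivariant under monotone transforms).
#'
#' @param days Time points (rows of the matrices).
#' @param replicates Named list of day x replicate matrices.
#' @param probs Envelope probabilities (default 2.5% and 97.5%).
#' @return An [EnsembleSummary-class].
#' @export
ensembleSummary <- function(days, replicates, probs = c(0.025, 0.975)) {
  vars <- names(replicates)
  n <- ncol(replicates[[1]])
  mk <- function(f) {
    m <- vapply(vars, function(v)
      apply(replicates[[v]], 1, f), numeric(length(days)))
    colnames(m) <- vars
    m
  }
  new("EnsembleSummary", days = days,
      mean = mk(function(x) mean(x, na.rm = TRUE)),
      lower = mk(function(x)
        stats::quantile(x, probs[1], na.rm = TRUE, type = 1, names = FALSE)),
      upper = mk(function(x)
        stats::quantile(x, probs[2], na.rm = TRUE, type = 1, names = FALSE)),
      replicates = replicates, nReplicates = n, probs = probs)
}

#' @describeIn ensemble Ensemble of cage runs: replicate \code{i} is
#'   \code{runCage(x, seed = baseSeed + i - 1)}; summarised variables are
#'   \code{prop_female}, \code{transgene_freq} and \code{eggs_laid} on the
#'   twice-weekly collection days.
#' @export
setMethod("ensemble", "CageProtocol", function(x, n = 100, baseSeed = 0, ...) {
  if (n < 2) stop("an ensemble needs at least 2 replicates")
  runs <- lapply(seq_len(n) - 1, function(i) samples(runCage(x, baseSeed + i)))
  days <- runs[[1]]$day
  grab <- function(v) vapply(runs, `[[`, numeric(length(days)), v)
  ensembleSummary(days, list(prop_female = grab("prop_female"),
                             transgene_freq = grab("transgene_freq"),
                             eggs_laid = grab("eggs_laid")))
})

#' @describeIn post45Summary Single cage run: mean and SE over qualifying
#'   collection days.
#' @export
setMethod("post45Summary", "CageSeries", function(x, threshold = 45) {
  s <- samples(x)
  s <- s[s$day > threshold, , drop = FALSE]
  if (nrow(s) == 0)
    stop("series does not extend past day ", threshold)
  summarise <- function(v) {
    v <- v[!is.na(v)]
    data.frame(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
               n_days = length(v))
  }
  out <- rbind(summarise(s$prop_female), summarise(s$transgene_freq))
  out$variable <- c("prop_female", "transgene_freq")
  out[c("variable", "mean", "se", "n_days")]
})

#' @describeIn post45Summary Ensemble: the mean pools all replicate-by-day
#'   values; the SE is the standard deviation of per-replicate means over
#'   the square root of the number of replicates.
#' @export
setMethod("post45Summary", "EnsembleSummary", function(x, threshold = 45) {
  keep <- x@days > threshold
  if (!any(keep)) stop("ensemble does not extend past day ", threshold)
  vars <- intersect(c("prop_female", "transgene_freq"), names(x@replicates))
  out <- do.call(rbind, lapply(vars, function(v) {
    m <- x@replicates[[v]][keep, , drop = FALSE]
    repMeans <- colMeans(m, na.rm = TRUE)
    data.frame(variable = v, mean = mean(m, na.rm = TRUE),
               se = stats::sd(repMeans) / sqrt(length(repMeans)),
               n_days = sum(keep))
  }))
  out
})

#' Fraction of observed points inside an ensemble envelope
#'
#' Compares observed proportions against the pointwise percentile band on
#' the shared collection days; points outside the band are tallied above
#' and below separately (validation against cage data found observations
#' often above the predicted band).
#'
#' @param observed Either an [ObservedSeries-class] (screen counts are
#'   converted to proportions) or a data.frame with columns \code{day} and
#'   \code{value}.
#' @param summary An [EnsembleSummary-class].
#' @param variable Which envelope variable to compare against (default
#'   \code{"prop_female"}).
#' @return List: \code{coverage}, \code{nAbove}, \code{nBelow}, \code{n}.
#' @export
envelopeCoverage <- function(observed, summary, variable = "prop_female") {
  if (is(observed, "ObservedSeries")) {
    o <- observations(observed)
    val <- switch(variable,
      prop_female = o$females / o$screen_n,
      transgene_freq = o$transgenics / o$screen_n,
      stop("no observed counterpart for variable ", variable))
    observed <- data.frame(day = o$day, value = val)
  }
  band <- envelopeBand(summary, variable)
  m <- merge(observed, band, by = "day")
  m <- m[!is.na(m$value) & !is.na(m$lower), , drop = FALSE]
  if (nrow(m) == 0) stop("no common time points between observations and band")
  above <- m$value > m$upper
  below <- m$value < m$lower
  list(coverage = mean(!above & !below), nAbove = sum(above),
       nBelow = sum(below), n = nrow(m))
}

#' Least-squares trend slope of a count series
#'
#' Ordinary least-squares regression of counts on day, as used to
#' summarise the decline in egg production over the release period.
#'
#' @param day Numeric vector of days.
#' @param count Counts (same length).
#' @param level Confidence level (default 0.95).
#' @return List: \code{slope}, \code{ci} (length 2), \code{se}.
#' @examples
#' trendSlope(0:2, c(100, 90, 80))$slope   # exactly -10
#' @export
trendSlope <- function(day, count, level = 0.95) {
  keep <- !is.na(day) & !is.na(count)
  day <- day[keep]; count <- count[keep]
  if (length(day) < 3) stop("need at least 3 points for a trend slope")
  fit <- stats::lm(count ~ day)
  ci <- stats::confint(fit, "day", level = level)
  list(slope = unname(stats::coef(fit)["day"]), ci = as.numeric(ci),
       se = unname(sqrt(stats::vcov(fit)["day", "day"])))
}
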