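#' @include AllClasses.R AllGenerics.R lifehistory.R
NULL

#' Read and write pmbpop data as plain text
#'
#' CSV/JSON serialisation for the package's data objects.  Daily-death
#' tables carry their metadata (initial_n, cages, censor_day) in a
#' commented header line; fitted lifespan models are stored as JSON;
#' series objects as flat CSV.
#'
#' @param x Object to write.
#' @param path File path.
#' @return Readers return the reconstructed object; writers return
#'   \code{invisible(path)}.
#' @name pmbpop-io
NULL

#' @rdname pmbpop-io
#' @export
writeDailyDeaths <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# initial_n=%d cages=%d censor_day=%d",
                     as.integer(x@initialN), as.integer(x@cages),
                     as.integer(x@censorDay)), con)
  utils::write.csv(x@records, con, row.names = FALSE)
  invisible(path)
}

#' @rdname pmbpop-io
#' @export
readDailyDeaths <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[0-9]+", hdr))[[1]]
  meta <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  rec <- utils::read.csv(path, comment.char = "#")
  dailyDeaths(rec, initialN = meta[["initial_n"]], cages = meta[["cages"]],
              censorDay = meta[["censor_day"]])
}

#' @rdname pmbpop-io
#' @export
writeLifespanModel <- function(x, path) {
  jsonlite::write_json(list(shape = x@shape, scale = x@scale, sex = x@sex),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pmbpop-io
#' @export
readLifespanModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lifespanModel(shape = j$shape, scale = j$scale, sex = j$sex)
}

#' @rdname pmbpop-io
#' @export
writeCageSeries <- function(x, path) {
  utils::write.csv(samples(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname pmbpop-io
#' @export
writeVillageSeries <- function(x, path) {
  utils::write.csv(daily(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname pmbpop-io
#' @param frequency Rainfall cadence when reading (\code{"weekly"} or
#'   \code{"daily"}); files written by [writeRainfall()] record it.
#' @export
writeRainfall <- function(x, path) {
  d <- data.frame(period = seq_along(rainfallMm(x)), mm = rainfallMm(x),
                  frequency = rainFrequency(x))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pmbpop-io
#' @export
readRainfall <- function(path, frequency = NULL) {
  d <- utils::read.csv(path)
  if (is.null(frequency))
    frequency <- if ("frequency" %in% names(d)) d$frequency[1] else "weekly"
  new("RainSeries", mm = d$mm, frequency = frequency)
}
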