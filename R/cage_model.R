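#' @include AllClasses.R AllGenerics.R genetics.R lifehistory.R
NULL

# Weekday convention: day 0 is a Monday.
.OVI_WDAYS <- c(0, 3)   # Mon, Thu: oviposition + restock sampling
.ADD_WDAYS <- c(1, 4)   # Tue, Fri: adult additions and releases

.isOviDay <- function(day) (day %% 7) %in% .OVI_WDAYS
.isAddDay <- function(day) (day %% 7) %in% .ADD_WDAYS

# Tue/Fri days in [from, to]
.addDaysBetween <- function(from, to) {
  d <- from:to
  d[.isAddDay(d)]
}

#' Build a large-cage trial protocol
#'
#' Encodes the two experimental designs.  Trial 1 seeded each cage with a
#' pre-existing stable-age population of 300 females and 178 males, then
#' added 60+60 adults twice weekly for 3 weeks and 50+50 twice weekly for a
#' further 3 weeks; transgenic-male releases began 6 weeks after initiation
#' and ran for two months.  Trials 2 and 3 established the target population
#' with 50+50 adults twice weekly for 4 weeks; releases then ran for four
#' months.  Releases are 50 (1:1) or 150 (3:1) hemizygous males every
#' Tuesday and Friday; the control receives none.
#'
#' @param trialStyle \code{"trial23"} (default) or \code{"trial1"}.
#' @param treatment \code{"control"}, \code{"ratio_1_1"} or
#'   \code{"ratio_3_1"}.
#' @param restockSampleSize Eggs kept per collection day (default 100).
#' @param developmentDays Oviposition-to-emergence delay (default 10).
#' @param eggsPerDay Poisson mean of viable eggs per female per permitted
#'   oviposition day (default 9).
#' @param maleBias Male probability under transgenic fathers (default 0.95).
#' @param lifespans List with \code{male} and \code{female}
#'   [LifespanModel-class] objects; default [defaultLifespans()].
#' @param postReleaseDays Observation days after the first release; defaults
#'   to 60 (trial 1, "two months") or 120 (trials 2-3, "four months").
#' @return A [CageProtocol-class].
#' @examples
#' buildProtocol("trial23", "ratio_3_1")
#' @export
buildProtocol <- function(trialStyle = c("trial23", "trial1"),
                          treatment = c("control", "ratio_1_1", "ratio_3_1"),
                          restockSampleSize = 100, developmentDays = 10,
                          eggsPerDay = 9, maleBias = 0.95,
                          lifespans = defaultLifespans(),
                          postReleaseDays = NULL) {
  trialStyle <- match.arg(trialStyle)
  treatment <- match.arg(treatment)
  if (trialStyle == "trial1") {
    wk3 <- .addDaysBetween(0, 20)          # 6 Tue/Fri days in weeks 1-3
    wk6 <- .addDaysBetween(21, 41)         # 6 Tue/Fri days in weeks 4-6
    est <- rbind(
      data.frame(day = 0, females = 300, males = 178, stationary = TRUE),
      data.frame(day = wk3, females = 60, males = 60, stationary = FALSE),
      data.frame(day = wk6, females = 50, males = 50, stationary = FALSE))
    releaseStart <- 42
    if (is.null(postReleaseDays)) postReleaseDays <- 60
  } else {
    est <- data.frame(day = .addDaysBetween(0, 27), females = 50, males = 50,
                      stationary = FALSE)
    releaseStart <- 28
    if (is.null(postReleaseDays)) postReleaseDays <- 120
  }
  releaseSize <- switch(treatment, control = 0, ratio_1_1 = 50,
                        ratio_3_1 = 150)
  new("CageProtocol", trialStyle = trialStyle, treatment = treatment,
      establishment = est, releaseSize = releaseSize,
      releaseStart = releaseStart,
      durationDays = releaseStart + postReleaseDays,
      restockSampleSize = restockSampleSize,
      developmentDays = developmentDays, eggsPerDay = eggsPerDay,
      maleBias = maleBias, maleLifespan = lifespans$male,
      femaleLifespan = lifespans$female)
}

## ---- internal state ---------------------------------------------------

# Adults are tracked as individuals in parallel vectors; juveniles as
# scheduled cohorts (genotype x sex count matrices keyed by emergence day).
.newCageState <- function() {
  list(
    m_gt = character(0), m_death = numeric(0),       # adult males
    f_gt = character(0), f_mate = character(0),      # mated females
    f_death = numeric(0), f_mated = numeric(0),      # .. death / mating day
    u_gt = character(0), u_death = numeric(0),       # unmated females
    cohorts = list())                                # emergence-day keyed
}

# death day: entry + ceiling(lifespan); the individual is absent from the
# day its (integer) age first exceeds its continuous lifespan
.deathDay <- function(entryDay, n, model) entryDay + ceiling(sampleLifespan(n, model))

#' Mate newly emerged females to random males
#'
#' Each female independently picks a mate uniformly at random among all
#' living adult males (equal mating competitiveness); the mate's genotype is
#' recorded permanently (single mating).  With no males present the females
#' remain unmated and retry the next day.
#'
#' @param femaleGt Genotypes of the females seeking mates.
#' @param maleGt Genotypes of the living adult males.
#' @return Character vector of mate genotypes (length 0 if no males).
#' @export
mateFemale <- function(femaleGt, maleGt) {
  if (length(maleGt) == 0) return(character(0))
  maleGt[sample.int(length(maleGt), length(femaleGt), replace = TRUE)]
}

# multivariate hypergeometric draw of k items from counts (without
# replacement), via sequential univariate hypergeometrics
.rmvhyper <- function(counts, k) {
  counts <- as.integer(counts)
  total <- sum(counts)
  k <- min(k, total)
  out <- integer(length(counts))
  remaining <- total
  for (i in seq_along(counts)) {
    if (k == 0) break
    xi <- stats::rhyper(1, counts[i], remaining - counts[i], k)
    out[i] <- xi
    k <- k - xi
    remaining <- remaining - counts[i]
  }
  out
}

#' Random restock sample from the day's egg pool
#'
#' Draws \code{min(k, total)} eggs without replacement across the
#' genotype-by-sex classes (multivariate hypergeometric), emulating the
#' random 100-egg sample kept to propagate the cage population.
#'
#' @param eggPool Genotype x sex count matrix of all eggs laid that day.
#' @param k Sample size (default 100).
#' @return Genotype x sex count matrix of the kept sample.
#' @export
sampleRestock <- function(eggPool, k = 100) {
  if (k <= 0) stop("restock sample size must be positive")
  out <- emptyBrood()
  out[] <- .rmvhyper(eggPool, k)
  out
}

# Add adults entering the cage (establishment, releases, emergence).
# Establishment/released adults are zero-age; trial-1 stationary seeds get
# residual lifetimes from the stable-age distribution and WT mates.
.addMales <- function(state, day, gt, n, protocol, stationary = FALSE) {
  if (n == 0) return(state)
  death <- if (stationary)
    day + ceiling(.sampleResidualLifespan(n, protocol@maleLifespan))
  else .deathDay(day, n, protocol@maleLifespan)
  state$m_gt <- c(state$m_gt, rep(gt, n))
  state$m_death <- c(state$m_death, death)
  state
}

## ---- daily step -------------------------------------------------------

# One simulated day. Order: deaths; emergence; additions + releases;
# mating of all unmated females; oviposition/restock on Mon & Thu; census.
.stepCageDay <- function(state, day, protocol, rec) {
  ## 1. deaths
  keep <- state$m_death > day
  state$m_gt <- state$m_gt[keep]; state$m_death <- state$m_death[keep]
  keep <- state$f_death > day
  state$f_gt <- state$f_gt[keep]; state$f_mate <- state$f_mate[keep]
  state$f_death <- state$f_death[keep]; state$f_mated <- state$f_mated[keep]
  keep <- state$u_death > day
  state$u_gt <- state$u_gt[keep]; state$u_death <- state$u_death[keep]

  ## 2. emergence of juveniles laid developmentDays ago
  key <- as.character(day)
  co <- state$cohorts[[key]]
  if (!is.null(co)) {
    state$cohorts[[key]] <- NULL
    nM <- co[, "M"]
    state <- .addGenotypeMales(state, day, nM, protocol)
    nF <- co[, "F"]
    if (sum(nF) > 0) {
      gts <- rep(GENOTYPES, nF)
      state$u_gt <- c(state$u_gt, gts)
      state$u_death <- c(state$u_death,
                         .deathDay(day, length(gts), protocol@femaleLifespan))
    }
  }

  ## 3. scheduled establishment additions and transgenic-male releases
  est <- protocol@establishment
  todays <- est[est$day == day, , drop = FALSE]
  if (nrow(todays)) {
    for (i in seq_len(nrow(todays))) {
      r <- todays[i, ]
      if (r$stationary) {
        # pre-existing stable population: females already mated (to WT),
        # ages from the stationary residual-lifetime distribution
        state <- .addMales(state, day, "WT", r$males, protocol,
                           stationary = TRUE)
        n <- r$females
        state$f_gt <- c(state$f_gt, rep("WT", n))
        state$f_mate <- c(state$f_mate, rep("WT", n))
        state$f_death <- c(state$f_death,
          day + ceiling(.sampleResidualLifespan(n, protocol@femaleLifespan)))
        state$f_mated <- c(state$f_mated, rep(day - 1, n))
      } else {
        state <- .addMales(state, day, "WT", r$males, protocol)
        state$u_gt <- c(state$u_gt, rep("WT", r$females))
        state$u_death <- c(state$u_death,
          .deathDay(day, r$females, protocol@femaleLifespan))
      }
    }
  }
  if (protocol@releaseSize > 0 && day >= protocol@releaseStart &&
      .isAddDay(day)) {
    state <- .addMales(state, day, "HEMI", protocol@releaseSize, protocol)
  }

  ## 4. mating: all currently unmated females try a uniform-random male
  if (length(state$u_gt) && length(state$m_gt)) {
    mates <- mateFemale(state$u_gt, state$m_gt)
    state$f_gt <- c(state$f_gt, state$u_gt)
    state$f_mate <- c(state$f_mate, mates)
    state$f_death <- c(state$f_death, state$u_death)
    state$f_mated <- c(state$f_mated, rep(day, length(mates)))
    state$u_gt <- character(0); state$u_death <- numeric(0)
  }

  ## 5. oviposition + restock sampling on collection days
  if (.isOviDay(day)) {
    eligible <- state$f_mated < day       # lay from the day after mating
    pool <- emptyBrood()
    eggsLaid <- 0
    if (any(eligible)) {
      cls <- table(factor(state$f_gt[eligible], GENOTYPES),
                   factor(state$f_mate[eligible], GENOTYPES))
      for (mo in GENOTYPES) for (fa in GENOTYPES) {
        n <- cls[mo, fa]
        if (n == 0) next
        ne <- stats::rpois(1, protocol@eggsPerDay * n)
        eggsLaid <- eggsLaid + ne
        pool <- pool + sampleBrood(ne, fa, mo, protocol@maleBias)
      }
    }
    restock <- sampleRestock(pool, protocol@restockSampleSize)
    if (sum(restock) > 0)
      state$cohorts[[as.character(day + protocol@developmentDays)]] <- restock
    rec$samples[[length(rec$samples) + 1L]] <- data.frame(
      day = day, eggs_laid = eggsLaid,
      restock_female = sum(restock[, "F"]),
      restock_male = sum(restock[, "M"]),
      restock_transgenic = sum(restock[c("HEMI", "HOMO"), ]),
      restock_total = sum(restock),
      prop_female = femaleFraction(restock),
      transgene_freq = transgenicFraction(restock))
  }

  ## 6. daily adult census
  rec$census[[length(rec$census) + 1L]] <- data.frame(
    day = day, adult_males = length(state$m_gt),
    mated_females = length(state$f_gt),
    unmated_females = length(state$u_gt),
    transgenic_adults = sum(state$m_gt != "WT") + sum(state$f_gt != "WT") +
      sum(state$u_gt != "WT"))
  state
}

.addGenotypeMales <- function(state, day, nByGt, protocol) {
  for (gt in GENOTYPES)
    state <- .addMales(state, day, gt, nByGt[[gt]], protocol)
  state
}

#' Run one cage trial
#'
#' Simulates the full protocol day by day from day 0 (a Monday) and returns
#' the observable series.  Deterministic for a given seed.
#'
#' @param protocol A [CageProtocol-class].
#' @param seed Integer seed for the run.
#' @return A [CageSeries-class].
#' @examples
#' s <- runCage(buildProtocol("trial23", "control"), seed = 1)
#' head(samples(s))
#' @export
runCage <- function(protocol, seed = 0) {
  set.seed(seed)
  state <- .newCageState()
  rec <- new.env(parent = emptyenv())
  rec$samples <- list(); rec$census <- list()
  for (day in 0:(protocol@durationDays - 1))
    state <- .stepCageDay(state, day, protocol, rec)
  new("CageSeries",
      samples = do.call(rbind, rec$samples),
      census = do.call(rbind, rec$census),
      protocol = protocol, seed = seed)
}

#' Deterministic mean-field equilibrium of the cage model
#'
#' Closed-form test oracle neglecting age structure, homozygotes and
#' transgenic mothers.  With O offspring recruited per week and R released
#' males per week, the equilibrium transgenic fraction p among males solves
#' \deqn{0.45\,O\,p^2 + (0.025\,O + R)\,p - R = 0,}
#' from which the offspring female fraction is \eqn{F = 0.5 - 0.45 p} and
#' the offspring transgene frequency \eqn{q = 0.5 p}.  The quadratic comes
#' from balancing recruitment: transgenic fathers sire 95% males, half of
#' them transgenic, so weekly male recruits number \eqn{O(0.5 + 0.45 p)} of
#' which \eqn{0.475\,O\,p} are transgenic, plus R released.
#'
#' @param weeklyOffspring O, offspring entering the adult pool per week
#'   (2 x restock sample under the default cadence).
#' @param weeklyRelease R, released males per week (2 x release size).
#' @return List with elements \code{p}, \code{F}, \code{q}.
#' @examples
#' meanFieldEquilibrium(200, 100)  # 1:1 cadence
#' @export
meanFieldEquilibrium <- function(weeklyOffspring, weeklyRelease) {
  O <- weeklyOffspring; R <- weeklyRelease
  if (O <= 0) stop("weeklyOffspring must be positive")
  if (R < 0) stop("weeklyRelease must be non-negative")
  if (R == 0) {
    p <- 0
  } else {
    a <- 0.45 * O; b <- 0.025 * O + R; cc <- -R
    p <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  }
  list(p = p, F = 0.5 - 0.45 * p, q = 0.5 * p)
}
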