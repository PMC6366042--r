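---
title: "Modelling paternal-male-bias transgene releases: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling paternal-male-bias transgene releases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmbpop)
```

`pmbpop` simulates releases of a paternal-male-bias (PMB) transgenic
mosquito strain into *Anopheles gambiae* populations, at two scales: a
large-cage trial and a rainfall-driven village population. This vignette
is the package's account of the models themselves — assumptions,
parameters, numerical choices, and the places where the design was
genuinely open.

## The shared demographic core

Both models track juveniles (by age, genotype, sex), unmated adult
females (by genotype), adult males (by genotype), and mated adult females
(by own and mate genotype). The rules:

* Juveniles emerge as adults 10 days after oviposition.
* A newly emerged female mates once, on her emergence day, with a male
  chosen uniformly at random among all living adult males (mating
  competitiveness of transgenic males is assumed equal to wild type: the
  underlying competition experiment found 54% of matings went to
  transgenic males, indistinguishable from parity). If no males are
  present she retries daily. Her mate's genotype is recorded permanently.
* A mated female lays a Poisson(9) number of viable eggs per permitted
  day (every day in the village; Mondays and Thursdays in the cage),
  starting the day *after* she mates — the protocol's blood-meal cadence
  implies at least a day's lag, and the choice removes an ambiguity about
  same-day laying.
* Egg genotypes are multinomial with exact single-locus Mendelian
  probabilities; each egg's sex is independently male with probability
  0.95 when the father carries the transgene (hemi- or homozygous) and
  0.5 otherwise. Mothers never bias the sex ratio. Genotype and sex are
  drawn independently: for an autosomal construct that is the only joint
  model consistent with a genotype multinomial and a sex binomial.
* The transgene carries no fitness cost in any life stage; homozygotes
  arise naturally from transgenic-by-transgenic matings and are modelled
  (a released male's granddaughters can be homozygous; the model permits
  the resulting 5%-female broods to matter demographically).

A population that starts without transgenic individuals and receives no
releases can never acquire the transgene — an absorbing state the test
suite checks.

## Cage model

The cage model is individual-based (populations are a few hundred
adults). Day 0 is a Monday. Oviposition and restock sampling happen
Mondays and Thursdays; adult additions and transgenic-male releases
Tuesdays and Fridays. On a collection day all eggs laid are pooled and a
multivariate-hypergeometric sample of 100 is kept; those juveniles all
survive and emerge 10 days later. Adults receive Weibull lifespans at
entry; an individual is removed on the first day its integer age exceeds
its continuous lifespan.

Two trial designs are encoded. Trials 2–3: 50 females + 50 males added
twice weekly for 4 weeks, then releases (0, 50 or 150 hemizygous males
twice weekly) for four months. Trial 1: a day-0 seed of 300 females + 178
males from a pre-existing stable population, 60+60 twice weekly for 3
weeks, 50+50 for 3 more, releases from day 42 for two months. For the
trial-1 seed the paper-level description gives only counts; we draw the
seed adults' remaining lifetimes from the stationary residual-lifetime
distribution implied by the Weibull lifespan (density S(t)/mu, inverted
numerically on a 4096-point grid) and take all seed females as already
mated to wild-type males. "Two/four months" of releases is interpreted as
60/120 days after the first release, configurable via
`postReleaseDays`. Newly added virgin adults join the same-day mating
pool, as do males released that day; this collapses the within-day
ordering ambiguity in favour of the experimental situation, where
restocked adults and released males entered the cage together.

Observables mirror the experiment: per collection day, total eggs laid
and the composition of the 100-egg restock sample, from which the
proportion female and the transgene frequency derive. Summaries use
collection days after day 45 (six weeks from target-population
initiation), matching the experimental summary window.

### The mean-field oracle

`meanFieldEquilibrium()` is a deterministic check on the simulator. At
equilibrium, with O offspring recruited and R males released per week,
the transgenic male fraction p solves

$$0.45\,O\,p^2 + (0.025\,O + R)\,p - R = 0,$$

giving offspring female fraction \(F = 0.5 - 0.45p\) and offspring
transgene frequency \(q = 0.5p\). It neglects age structure, homozygotes
and transgenic mothers. The simulation converges to it late in a run: for
the 1:1 cadence (O = 200, R = 100) the ensemble proportion female over
collection days after day 130 is ≈ 0.23 against the oracle's 0.220.
Earlier windows sit above it, because the post-day-45 window still
contains the trial's settling transient: the ~400 wild-type establishment
males (median lifespan 28 d) and the females they mated before releases
dominate egg production for several weeks. Window means for the 1:1 arm
are therefore a few points above both the oracle and the corresponding
experimental mean; the 3:1 arm, which equilibrates faster, is not
affected. We report this as a property of the protocol + window
combination rather than adjusting either.

## Life-history module

Adult lifespans are Weibull. Defaults use shape 4 for both sexes with
scales set so the medians equal the experimental 28 d (males) and 30 d
(females): scale = median / (ln 2)^(1/4) ≈ 30.69 / 32.88 d. The source
experiment does not print fitted shape/scale; shape 4 was chosen so that
only ~3% of males and ~7% of females survive to the 42-day censoring
horizon, consistent with "almost all dead" at 42 d, and it is
configurable everywhere.

`fitWeibullCensored()` maximises the censored Weibull likelihood with
`survival::survreg`: a death recorded on day d contributes an
interval-censored term on (d−1, d] — the experiment records daily counts,
not exact times — and survivors at the censoring day contribute
right-censored terms. Fits are per sex (the sexes differ significantly in
the source data; pooling is possible by relabelling). Parameter-recovery
tests close the loop against the synthetic-experiment generator at the
experimental size (12 cages × 30 per sex: fitted median within ±1.5 d)
and in the exponential special case at n ≈ 2000 (shape within ±0.15).
Larval-stage life-table constants (8.5% larval mortality, median 7-day
duration, 6.6% pupal mortality) are recorded for the data generators but
deliberately *not* used by the cage model, whose juveniles all survive —
fidelity to the model being reproduced, not an oversight.

## Village model

The village model is count-based (populations reach hundreds of
thousands), with binomial/multinomial transitions over aggregated
classes, so a 3-year run costs a fraction of a second. Daily order:
juvenile thinning, emergence and same-day mating, adult survival,
releases, oviposition. Juveniles die each day with density-independent
probability 0.05 and survive competition with probability
\((\alpha(t)/(\alpha(t)+J_T))^{1/10}\), using the start-of-day total
\(J_T\) (synchronous update). The printed source formula labels this
quantity "mortality risk per day", but it equals 1 at \(J_T = 0\) and
composes over 10 days to the stated one-half death probability at
\(J_T = \alpha\) only when read as a daily *survival*; the package
implements that reading. Adults have constant daily survival — males 0.77
by default (field mark-release-recapture range 0.69–0.87), females
0.875 — so male age, though conceptually tracked in the source model, is
demographically inert and the state aggregates it away. Unmated females
(who mate the same day whenever any male exists) are not subjected to
mortality in their at-most-transient unmated state.

### The carrying-capacity driver

The exact functional form linking rainfall and water courses to
\(\alpha(t)\) lives in an upstream metapopulation model we could not
obtain, so the driver is pluggable with a documented default:

$$\alpha(t) = c\,\bigl(L + r\,\bar R_{14}(t)\bigr),$$

with L = 5 (permanent water courses, the dry-season floor), r = 2, and
\(\bar R_{14}\) the trailing 14-day mean of (weekly, repeated-to-daily)
rainfall. These give a ~18-fold wet:dry seasonal swing in carrying
capacity. The global scale c is never hand-set: `calibrateAlpha()`
bisects on log c until the unperturbed adult-female count at the end of
the rainy season (day 304 of the first post-burn-in year; the end of the
calendar year, day 365, is also reported by runs) matches a target —
35,500 for the Bana-like default — within 5%, averaging 5 seeded
replicates per evaluation.

Initialisation is arbitrary (1,000 wild-type mated females, 1,000 males,
proportional juveniles) and is erased by the 2-year burn-in; releases,
built by `makeSchedule()`, start on day 731. Schedules at weekly,
fortnightly, monthly (28-day) and quarterly (91-day) intervals over a
364-day release year carry identical cumulative totals by construction,
so frequency comparisons isolate the interval itself. There is no
migration.

### What the village model reproduces, and what it does not

After calibration the model reproduces the qualitative release
predictions: substantial female suppression at plausible weekly release
sizes, diminishing returns in release size (concave suppression curve),
near-insensitivity to release frequency at equal totals, and stronger
transgene persistence at higher male survival. Quantitatively it
suppresses *more* than the projections it emulates: ~36% end-of-season
reduction at 5,000/week (vs ~25%) and ~7,900 females left at 50,000/week
(vs ~13,500). The mechanism is visible in the trajectories: under the
synthetic rainfall defaults (60 mm/week peak, 1 mm/week dry floor) the
dry-season population is small, so releases running from 1 January drive
the transgenic male fraction above one half before the wet season begins,
and the population enters its growth phase already suppressed. The
upstream driver evidently sustains a larger dry-season population
relative to its wet-season peak. The suppression numbers are therefore
sensitive to the dry-season floor (L, and the dry rainfall floor) — a
parameter region the available sources do not pin down; we fixed the
defaults once, report the model's own numbers, and flag the sensitivity
rather than retrofitting the coefficients.

## Synthetic data generators

`genSurvivalExperiment()` reproduces the survival experiment's design (12
cages × 30 + 30 adults, daily counts, 42-day censoring) from any lifespan
models. `genRainfall()` produces weekly rainfall from a wrapped-Gaussian
seasonal profile (peak day 213 ≈ 1 August, width 60 d) with
mean-preserving multiplicative lognormal noise (CV 0.3), emulating a
Burkina Faso-like unimodal wet season; it does not emulate dry spells
within the wet season, interannual trends, or spatial structure.
`genObservedSeries()` corrupts a simulated cage series with the
experiment's sampling design (≈200-egg hatch samples, ≈100-individual
offspring screens) using unbiased binomial noise, with a beta-binomial
`rho` hook for the overdispersion that field monitoring methods such as
ovitraps are known to produce. Every generator is deterministic given its
seed. Passing tests on these inputs show the machinery is self-consistent
— they cannot show that the generators match any particular field site's
data.

## Numerical and testing choices

* Randomness: every run takes an integer seed (`set.seed` internally);
  ensembles use consecutive seeds from a base. Ensemble envelopes are
  pointwise order statistics (`quantile(type = 1)`, 2.5/97.5%), so they
  commute with monotone transforms; 100 replicates by default, matching
  the 95%-band-of-100-simulations construction being emulated.
* Death timing: lifespans are continuous; an adult is removed on the
  first day its integer age exceeds the drawn lifespan. Restock samples
  are multivariate hypergeometric via sequential `rhyper`. Brood class
  totals use the Poisson-sum identity (one draw per female class, not per
  female).
* Degenerate inputs error early and informatively: negative egg counts,
  death tables with no events or a single death day (shape
  unidentifiable), non-positive calibration targets, rainfall series
  shorter than the simulation, envelope comparisons with no shared days.
* Test problem sizes: 100-replicate cage ensembles and 5-replicate
  3-year village runs — the sizes the summaries themselves are defined
  over; Monte-Carlo checks use 10^4–10^5 draws with fixed seeds and
  tolerances set from binomial/multinomial sampling error.

## Known limitations

Single species and single population (no *An. gambiae* complex mixture,
no migration, no epidemiology); no egg-hatch-rate or rDNA-damage
dynamics; cage model has no juvenile mortality by construction; the
village driver's coefficients are a documented stand-in, with absolute
suppression levels sensitive to the dry-season carrying-capacity floor as
discussed above.
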