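# pmbpop

Stochastic population models for releases of a paternal-male-bias (PMB)
transgenic strain of *Anopheles gambiae*.

A PMB strain carries an autosomal transgene whose male carriers sire ~95%
male progeny (an I-PpoI nuclease shreds the X-bearing sperm's rDNA target),
half of which inherit the transgene. Repeated releases of transgenic males
therefore push a target population's sex ratio toward males and suppress
egg production, while the transgene itself persists under only weak
negative selection. `pmbpop` implements the two simulation models used to
evaluate this strategy, for modellers and trial designers who want to
reproduce, probe or extend those predictions:

- a **cage model**: daily-step, individual-based simulation of large-cage
  release trials against stable-age-distribution target populations
  (twice-weekly oviposition, 100-egg restocking, scheduled transgenic-male
  releases, Weibull adult lifespans);
- a **village model**: daily-step, count-based simulation of a single
  West-African village population with rainfall-driven density-dependent
  larval competition, constant adult daily survival, a two-year burn-in
  and year-three release experiments over release size and frequency.

Both share a demographic core: juveniles emerge as adults 10 days after
oviposition; females mate once, with a uniformly random male, on their
emergence day; mated females lay Poisson(9) viable eggs per permitted day;
egg genotypes are multinomial under Mendelian single-locus inheritance and
egg sex is binomial with male probability

```
P(male) = 0.95 if the father is hemi- or homozygous, 0.5 otherwise.
```

Around the core sit the supporting pieces: Weibull lifespan models with
interval/right-censored maximum-likelihood fitting from daily death
counts; synthetic-data generators (12-cage survival experiment, Sahelian
rainfall, binomial observation noise); and ensemble summaries (pointwise
2.5–97.5% envelopes over 100 seeded runs, post-day-45 means ± SE, OLS
trend slopes, envelope coverage) for comparing model and experiment.

In the village model, daily juvenile survival from competition is

```
s(J_T) = (alpha(t) / (alpha(t) + J_T))^(1/10)
```

so that survival over the 10-day development composes exactly to
`alpha/(alpha+J_T)`: `alpha(t)` is the juvenile count at which cumulative
competition mortality is one half. It is driven by trailing rainfall with
a permanent-water floor and calibrated (`calibrateAlpha()`) so the
unperturbed end-of-rainy-season population matches a target (~35,500
females for the Bana-like default).

## Worked example

```r
library(pmbpop)

## cage trial, trials-2/3 design, 3:1 release ratio
p <- buildProtocol("trial23", "ratio_3_1")
s <- runCage(p, seed = 1)
post45Summary(s)
#>         variable      mean         se n_days
#> 1    prop_female 0.1789655 0.01686913     29
#> 2 transgene_freq 0.3896552 0.02305211     29
```

After six weeks, offspring samples from the 3:1 cage are ~18% female
(control cages sit at ~50%) and ~39% of sampled offspring carry the
transgene — the released males' sons keep distorting the sex ratio long
after each release. The deterministic mean-field oracle for the same
cadence gives the equilibrium the simulation fluctuates around:

```r
meanFieldEquilibrium(weeklyOffspring = 200, weeklyRelease = 300)
#> $p 0.796434   # transgenic fraction among males
#> $F 0.1416047  # proportion female among offspring
#> $q 0.398217   # transgene frequency among offspring
```

A village release experiment:

```r
rain <- genRainfall(4, seed = 7)                 # synthetic Sahelian rainfall
cal  <- calibrateAlpha(villageConfig(), rain, seed = 100)
run  <- runVillage(cal$config, rain, makeSchedule(65000, "weekly"),
                   years = 3, seed = 100)        # 5,000 males / week, year 3
daily(run)[cal$measureDay, c("females", "transgenic_males")]
#>      females transgenic_males
#> 1034   22569             7977
```

Weekly releases of 5,000 males leave ~22,600 females at the end of the
release-year rainy season, against ~35,000 unperturbed — roughly a third
fewer, with ~8,000 transgenic males still present.

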