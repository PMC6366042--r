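# Shared expensive fixtures, built once per test run on first use.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# 100-replicate cage ensembles under the trials-2/3 protocol, seeds 0..99
cageEnsemble100 <- function(treatment) {
  memo(paste0("ens_", treatment),
       ensemble(buildProtocol("trial23", treatment), n = 100, baseSeed = 0))
}

# synthetic rainfall + calibrated village configuration shared across tests
villageFixture <- function() {
  memo("village", {
    rain <- genRainfall(4, seed = 7)
    cal <- calibrateAlpha(villageConfig(), rain, seed = 100)
    list(rain = rain, config = cal$config, achieved = cal$achieved,
         measureDay = cal$measureDay)
  })
}

# mean end-of-rainy-season female count over 5 seeded replicates
villageEosFemales <- function(schedule, seeds = 100:104) {
  vf <- villageFixture()
  mean(vapply(seeds, function(s)
    daily(runVillage(vf$config, vf$rain, schedule, years = 3,
                     seed = s))$females[vf$measureDay], numeric(1)))
}
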