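Package: pmbpop
Title: Stochastic Population Models for Paternal-Male-Bias Transgenic Mosquito Releases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stage-structured stochastic simulation of releases of a
    paternal-male-bias (PMB) sex-ratio-distorter transgenic strain of
    Anopheles gambiae. Implements a daily-step model of large-cage release
    trials against stable-age-distribution target populations, and a
    rainfall-driven village population model with density-dependent larval
    competition. Includes Mendelian transgene genetics with paternal sex
    distortion, Weibull adult-lifespan models with right/interval-censored
    maximum-likelihood fitting, synthetic data generators (survival
    experiments, Sahelian rainfall, observation noise), and ensemble
    percentile-envelope summaries for model validation against cage
    observations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'lifehistory.R'
    'genetics.R'
    'cage_model.R'
    'io.R'
    'reporting.R'
    'synthetic_data.R'
    'village_model.R'
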