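Package: quadratdyn
Title: Multispecies Demography and Climate-Perturbation Analysis for Mapped
    Chart Quadrats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing long-term mapped ('chart') quadrat records of
    perennial plants: tracking genet identities across yearly polygon maps,
    computing Gaussian-kernel neighbourhood crowding indices, fitting
    mixed-effects vital-rate models (survival, growth, recruitment) with
    climate covariates, and projecting community dynamics with a spatially
    explicit individual-based model and a spatially implicit multispecies
    integral projection model. Includes estimation of invasion growth rates
    and negative frequency dependence, and climate-perturbation experiments
    that decompose species' equilibrium-cover responses into direct and
    indirect (competition-mediated) effects. A synthetic-data generator
    produces ground-truth-parameterised quadrat archives and climate series
    so the whole pipeline can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmmTMB,
    lme4,
    nlme,
    pracma,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
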