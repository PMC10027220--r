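Package: pmadjoint
Title: Adjoint Source Attribution of PM2.5-Related Premature Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale adjoint-based source-attribution system for fine
    particulate matter (PM2.5) health burdens. A toy monthly steady-state
    chemical-transport model maps gridded multi-species, multi-sector
    emissions and boundary inflow to surface PM2.5 component concentrations;
    satellite-style fields correct and downscale the exposure; a GBD-style
    exposure-response model converts exposure into cause-specific premature
    deaths. The discrete adjoint of the full chain yields sensitivities of
    total deaths to every (species, month, grid cell) emission, from which
    contribution ledgers by species, sector, country and month, extra-regional
    splits via boundary perturbation, contribution-ratio maps, emission
    counterfactuals and uncertainty bounds are computed. All inputs are
    produced by a seeded synthetic-world generator that emulates the
    statistical structure of the real inventories, population, mortality and
    satellite products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
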