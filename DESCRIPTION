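Package: n2opart
Title: Partitioning Soil N2O Emissions into Microbial Sources from
    Isotopocule and 15N Gas-Flux Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the contributions of bacterial denitrification, fungal
    denitrification, nitrification, and nitrifier denitrification to soil N2O
    emissions by fusing natural-abundance N2O isotopocule measurements
    (site preference and delta-18O) with 15N gas-flux constraints (the source
    partitioning coefficient and the N2O product ratio). Provides isotopocule
    algebra and Rayleigh closed-system fractionation primitives, 15N gas-flux
    calculations based on the binomial two-pool non-equilibrium isotopologue
    model, a constrained Monte Carlo linear-system solver, a Bayesian
    Metropolis-Hastings mixing-and-fractionation sampler on the probability
    simplex, and a forward simulator of jar-incubation experiments for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
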