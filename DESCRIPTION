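Package: nitroxsim
Title: Abiotic Nitrogen Chemistry and Process Metrics for Acidic Ammonia
    Oxidation Reactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the abiotic nitrogen chemistry of acidic ammonia
    oxidation (nitritation) reactors treating high-strength streams such
    as source-separated urine. Provides acid-base speciation of the
    ammonium/ammonia and nitrite/nitrous-acid pairs with ionic-strength
    correction, the chemical nitrite oxidation reaction network (nitrous
    acid disproportionation, nitric oxide oxidation, nitrogen dioxide
    hydrolysis and the dinitrogen trioxide pathway), gas stripping of
    volatile nitrogen oxides, a driven continuous stirred-tank reactor
    simulation, Nash-Sutcliffe model efficiency, nitrite accumulation
    ratio and nitrogen balance metrics, Monod and non-competitive
    inhibition activity factors, and a seeded generator of synthetic
    reactor-operation timelines with realistic process disturbances.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
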