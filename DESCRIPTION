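Package: swarmsafe
Title: Population-Dynamic Models of Safeguard Control in Encapsulated
    Engineered Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ordinary differential equation models of collective survival
    and safeguard control for engineered bacteria encapsulated in permeable
    microcapsules ("microbial swarmbots").  Implements the bistable
    density-dependent survival model and its two-compartment extension, the
    full beta-lactamase (BlaM) antibiotic-degradation circuit model in
    dimensional and dimensionless form, and the two-compartment swarmbot
    model with membrane transport and pulsed medium dosing.  Analysis layers
    locate and classify steady states (including the critical survival
    threshold), quantify safeguard effectiveness by the area under the
    inside-minus-outside density difference, and map the three-region
    (no-safeguard / safeguard / extinction) phase diagram over antibiotic and
    nutrient feed concentrations.  A synthetic-data generator emulating
    fluorescence time-lapse read-outs and a trajectory least-squares fitting
    pipeline make parameter recovery testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
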