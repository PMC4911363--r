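Package: leafwue
Title: Dynamic Leaf Gas-Exchange Simulation and Water Use Efficiency Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates diurnal leaf gas exchange of a well-watered C3 leaf
    (parameterised for cucumber) by coupling dynamic stomatal conductance
    kinetics, Farquhar-von Caemmerer-Berry photosynthesis with mesophyll
    conductance solved through an analytical cubic, a mesophyll water and
    solute balance, and a Penman-Monteith leaf energy balance. Provides
    sinusoidal "ideal day" climate forcing generators, stomatal induction
    curve fitting for the kinetic parameters, and sensitivity scans of daily
    water use efficiency with respect to stomatal speed, maximum stomatal
    conductance, mesophyll conductance, and light fluctuation period.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
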