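Package: aquaflow
Title: Stopped-Flow Osmotic Permeability and Aquaporin Inhibition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of stopped-flow light-scattering experiments on cell
    suspensions: forward simulation of osmotic cell-volume kinetics under
    impermeant and permeant solute gradients, synthetic scattering-trace
    generation with known ground truth, single/double exponential and
    linear-slope rate fitting, conversion of rate constants to osmotic water
    (Pf) and solute (Pgly, Purea) permeability coefficients, dose-response
    IC50 Hill fitting, incubation time-course inhibition analysis, Arrhenius
    activation-energy estimation, and a channel-plus-bilayer two-pathway
    permeability decomposition.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
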