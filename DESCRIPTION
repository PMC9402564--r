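Package: afhomeo
Title: Maximum-Entropy Length Distributions of Actin Filaments Under
    Tensional Homeostasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-mechanics model of the length distribution of
    actin filaments in a cell maintaining tensional homeostasis. A
    two-term entropy (Shannon-type formation entropy of the monomer
    partition plus a dispersion entropy counting cytoplasmic compartment
    coverage) is maximized under constraints of a fixed monomer pool and
    a fixed expected filament tension, yielding a Boltzmann-like closed
    form for the probability that a monomer belongs to each length
    class. The package provides the closed-form solution, an independent
    variational oracle (exact multinomial state counts, Lagrangian
    stationarity residuals, and an equality-constrained Newton
    maximizer), scripted parameter sweeps with machine-checkable trend
    assertions, and deterministic tab-separated output for reproducible
    pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
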