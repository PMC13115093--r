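Package: mnptools
Title: Analysis Pipeline for Tea-Derived Micro-Nanoparticle Isolation and
    Binding Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising colloidal micro-nanoparticle fractions
    isolated from tea infusions by ultrafiltration and centrifugation.
    Implements TOPSIS multi-criteria ranking of separation conditions from
    dynamic light scattering read-outs (Z-average, count rate, PDI, zeta
    potential, conductivity), Stern-Volmer and double-logarithmic
    fluorescence-quenching fits for apparent binding constants, MM/GBSA
    component-energy aggregation and decomposition bookkeeping, Welch t-tests
    from summary statistics, and delta/range summaries of environmental
    stability sweeps. A seeded synthetic-data generator emulates every input
    table so the whole pipeline is testable without instrument data, and a
    command-line dispatcher wires the stages together.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
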