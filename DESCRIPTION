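Package: dybe
Title: Dual-Kinetic Simulation and Nearest-Neighbor Inference for
    DNA-PAINT with Dynamic Binder Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for DNA-PAINT super-resolution
    experiments that keep DNA-conjugated binders in solution during
    acquisition (dynamic binder exchange, DyBE).  Provides an event-driven
    simulator of the two coupled kinetic layers (reversible binder-target
    exchange and transient imager-docking hybridization), a synthetic
    localization-data generator with Picasso-dialect HDF5 and CSV I/O,
    nearest-neighbor-distance statistics with complete-spatial-randomness
    references, cross-NND labeling-efficiency estimation, NND-based
    stoichiometry decomposition of monomer/dimer mixtures, and condition
    scans over binder off-rates and probe concentrations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    RANN,
    igraph,
    rhdf5,
    yaml,
    jsonlite,
    readr,
    withr,
    digest,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
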