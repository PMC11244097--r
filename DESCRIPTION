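Package: emulgelopt
Title: Response-Surface Design and Desirability Optimization for Emulgel Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native workbench for optimizing semi-solid emulgel
    formulations by response-surface methodology. Builds face-centred central
    composite designs over formulation factors, fits coded-factor polynomial
    models with the diagnostics used in design-of-experiments practice
    (PRESS and predicted R-squared, adequate precision, partial F tests,
    hierarchical backward elimination), optimizes multiple responses through
    Derringer-Suich desirability functions, analyses in-vitro release
    time-series (sampling-replacement correction, first-order kinetics,
    release flux) and rheological temperature sweeps (sol-gel transition
    detection), and provides tie-corrected nonparametric tests. A synthetic
    data generator emulates replicate response tables, release profiles,
    storage-modulus sweeps and oil-droplet size distributions so the whole
    pipeline runs without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
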