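Package: monolayr
Title: Analysis of Langmuir Monolayer Compression Isotherms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing Langmuir monolayer compression isotherms of
    membrane phospholipids: surface pressure and compressibility-modulus
    (Cs^-1) computation, detection of lift-off, liquid-expanded to
    liquid-condensed transition and collapse, surface-potential and apparent
    dipole-moment readouts, and control-versus-compound comparison tables
    (fold reductions, percent changes). Includes a synthetic isotherm
    generator built on the Volmer equation of state and a constant-elasticity
    condensed branch, so the full pipeline can be validated against injected
    ground truth without laboratory data.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
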