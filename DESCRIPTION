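Package: rollcompactr
Title: Roll Compaction Material Libraries: Powder Descriptors, Ribbon
    Quality Models and Latent-Variable Design Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing roll compaction (dry granulation)
    material libraries. Computes SeDeM-style powder descriptors from raw
    instrument measurements, ribbon porosity and tensile strength from
    oil-intrusion and three-point bending records, fits the
    Ryshkewitch-Duckworth strength-porosity and power strength-pressure
    models with applicability screening, classifies materials by their
    roll compaction behaviour (RCBCS categories), fits multi-response
    NIPALS partial least squares models with cross-validated diagnostics
    and variable importance in projection (VIP), and maps ribbon quality
    targets into latent-variable score space to obtain a multi-objective
    design space. Includes a synthetic material-library generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
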