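Package: chpka
Title: Carbon-Hydrogen Acidity Prediction from Deprotonation Energies and
    Sorted-Charge Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Enumerates symmetry-distinct C-H deprotonation sites in organic
    molecules, computes heterolytic deprotonation free energies through a
    pluggable energy backend, calibrates them to pKa values in DMSO via an
    empirical linear fit with iterative outlier rejection, and trains
    gradient-boosted atom-level models on sorted partial-charge shell
    descriptors to predict C-H pKa values and likely reaction sites.
    Molecule handling is delegated to Open Babel; a deterministic surrogate
    energy backend and charge provider allow the full workflow to run and be
    tested without any quantum-chemistry engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
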