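Package: granulosim
Title: Simulation of Human Granulopoiesis Under Chemotherapy and G-CSF
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compartmental pharmacokinetic/pharmacodynamic model of human
    granulopoiesis under cytotoxic chemotherapy with G-CSF support
    (Filgrastim or Pegfilgrastim).  Chemotherapy toxicity is modelled
    phenomenologically through delayed first-order cell-loss terms with
    drug-, dose- and cell-stage-specific toxicity coefficients, including a
    first-cycle effect and a lymphocyte sub-model.  The package ships a
    machine-readable library of common regimens (CHOP, CHOEP, BEACOPP, TA,
    ETC, EC-T, ESHAP and others) together with reference toxicity parameter
    sets, quantifies myelotoxicity as the area over the curve (AOC) below a
    threshold, estimates toxicity parameters from median blood-count time
    series by an evolutionary strategy, and evaluates alternative G-CSF
    schedules on AOC grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
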