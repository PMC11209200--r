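Package: fugascreen
Title: Environmental Fate and Hazard Screening of Nematicidal Volatiles
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Comparative ecotoxicological screening of candidate bionematicides
    against synthetic nematicides. Ingests and validates physicochemical
    property tables, estimates missing partition parameters (Seth organic
    carbon/water partition coefficient from Kow, Henry's law constant from
    vapour pressure, molar mass and aqueous solubility, and the solid-phase
    fugacity ratio), computes the predicted environmental distribution of a
    fixed emission with a Level I Mackay fugacity model in a standard
    evaluative environment, classifies acute mammalian toxicity into GHS
    hazard categories and toxicity-class bands, and joins exposure with
    hazard into a transparent, rule-based screening report. Includes a
    synthetic compound and endpoint-table generator for pipeline testing and
    parameter-recovery checks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
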