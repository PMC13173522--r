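Package: domfrag
Title: Chromatographic and Tandem-MS Fragmentation Metrics for
    Carboxyl-Rich Dissolved Organic Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing carboxyl-rich dissolved organic
    matter (DOM) by negative-mode liquid chromatography tandem mass
    spectrometry. Implements exact-mass CHO formula arithmetic and
    formula assignment, extracted-ion-chromatogram (XIC) handling with
    the cumulative-intensity retention metric (%CI) and its percentile
    elution profiles, and four per-spectrum fragmentation metrics
    (%Parent, %FG, Avg Frag, %Radical) built on sequential
    CO2/H2O/CH4O neutral-loss enumeration, odd-electron radical-anion
    detection and mass-defect filtering of likely halogenated
    contaminants. A seeded synthetic-data generator produces DOM-like
    MS1 runs and HCD MS2 spectra with per-peak ground truth for
    validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
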