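Package: nadhreg
Title: Electroanalytical Toolkit for Mediated NADH Regeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the electrochemical regeneration of the
    enzymatically active cofactor 1,4-NADH mediated by the rhodium complex
    [Cp*Rh(bpy)Cl]+. Provides readers for tabular potentiostat and
    spectrophotometer exports; cyclic-voltammetry peak detection and
    Nicholson-Shain peak-shift kinetics (transfer-coefficient product
    alpha*n); equivalent-circuit fitting of electrochemical impedance
    spectra with constant-phase and Warburg elements and effective
    capacitances; the two-wavelength enzyme-assay quantification of active
    1,4-NADH; derived regeneration metrics (selectivity, Faraday
    efficiency, specific production rate); and seeded synthetic-data
    generators, including a finite-difference simulator of irreversible
    voltammetry, so that every stage can be exercised against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
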