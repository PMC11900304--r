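Package: tearmrm
Title: Targeted MRM Quantification of Tear Proteins Sampled on Schirmer Strips
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of a targeted
    bottom-up proteomics workflow for quantifying albumin, lactoferrin and
    lysozyme in human tears collected on Schirmer strips, with non-human
    homolog proteins as internal standards. Provides monoisotopic peptide and
    b/y fragment-ion mass calculus with in-silico tryptic digestion; design
    and analytic verification of MRM transition tables; a seeded synthetic-data
    generator emulating tear samples, strip wetting, buffer-dependent
    extraction and a linear MRM instrument response; internal-standard
    response-ratio calibration and back-calculation; and bioanalytical method
    validation statistics (recovery, matrix effect, bias, CV, LOD/LOQ,
    wetted-length-to-volume conversion, direct-versus-strip method comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
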