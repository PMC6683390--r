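Package: hpadeconv
Title: Specificity Deconvolution for Bead-Array Platelet Antibody Assays
Version: 0.1.0
Authors@R:
    person("Transfusion", "Informatics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for glycoprotein-capture bead-array assays that
    detect human platelet antigen (HPA) and HLA class I antibodies in a single
    well. Computes per-bead positivity cutoffs from negative-control sera
    (mean + 3 SD), calls bead-by-donor reactivity from median fluorescence
    intensities, and deconvolves antibody specificities from reactivity
    patterns over a panel of HPA-genotyped platelet donors using a minimal
    consistent-set search with population-frequency priors. Includes
    serial-dilution endpoint-titer analysis with conversion to IU/mL against a
    reference-standard potency, a synthetic assay simulator for end-to-end
    validation, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
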