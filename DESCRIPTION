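Package: parascreen
Title: Diagnostic Fragment Ion Screening of Parabens and Phenolic
    Metabolites in LC-HRMS Non-Targeted Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Non-targeted LC-HRMS screening of parabens
    (4-hydroxybenzoate esters), their phase I metabolites (alkyl
    protocatechuates, phenolic acids) and phase II conjugates in negative
    electrospray data. Provides a curated registry of diagnostic HCD
    fragment ions with their fragmentation-pathway graph, bounded
    elemental-formula decomposition under RDBE constraints, precursor
    prioritization for data-dependent (ddMS2) and data-independent (AIF)
    acquisition, sulfate/glucuronide/glycine conjugate screening with
    hydrolyzed-versus-unhydrolyzed speciation calls, a linear QSRR
    retention-time model over 2D molecular descriptors, spectral-library
    cosine matching, Schymanski-scale confidence assignment, QA/QC
    estimators (IDL, MDL, recovery, matrix effect, RSD), and a seeded
    mzML simulator of spiked-biofluid runs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
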