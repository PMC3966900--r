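Package: panelkit
Title: Hotspot Mutation Panel Design and MALDI-TOF Genotyping Simulation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing and validating mass-spectrometry based
    somatic hotspot mutation panels, modelled on a 13-gene gynaecological
    cancer panel (171 mutations, 99 iPLEX assays, 13 multiplex wells).
    Implements hotspot-gene selection from a COSMIC-like mutation catalogue,
    multiplex assay packing under analyte mass-separation constraints,
    panel coverage and expected mutation-yield prediction, an in-silico
    MALDI-TOF two-allele peak simulator with noise, salt-adduct artifacts
    and DNA-quality dependent failures, threshold-based mutant allele
    fraction calling, replicate confirmation, cross-platform concordance
    against allele-specific qPCR, and tissue-stratified mutation spectrum
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
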