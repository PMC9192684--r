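Package: rfiprot
Title: Feed-Efficiency Scoring and Label-Free Proteomics for Dairy Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for residual feed intake (RFI) phenotyping of lactating
    dairy cows and downstream adipose-tissue proteomics. Computes
    energy-corrected milk, NRC-style predicted dry matter intake, RFI and
    efficiency classification from daily performance records; quantifies
    proteins from peptide intensities by total-ion-current normalization
    and top-3 peptide rollup with PCA quality control; calls differentially
    abundant proteins with equal-variance t-tests and signed fold changes;
    performs hypergeometric term enrichment against GMT annotation sets;
    and computes delta-delta-Ct relative expression with reference-gene
    stability selection. Seeded synthetic-data generators with known ground
    truth close the testing loop for every stage, and a pipeline runner
    orchestrates the stages end to end with a hashed output manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
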