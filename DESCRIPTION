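Package: driverstrength
Title: Patient-Level Cancer Driver Event Integration and Driver Strength Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates somatic single-nucleotide alterations, copy-number
    alterations and arm/chromosome-level aneuploidy into per-patient driver
    events for TCGA-style pan-cancer cohorts, classifies each gene-level event
    into oncogene and tumour-suppressor classes, and ranks drivers by the
    Driver Strength Index (DSI) and its frequency-normalized form (NDSI),
    which up-weight genes altered in patients carrying few driver events
    overall. Includes expression-based validation of copy-number calls,
    a hyperactivating-to-inactivating mutation ratio for gene polarity,
    bootstrap calling of cohort-level aneuploidy drivers with
    Benjamini-Hochberg control, multi-source consensus filtering of driver
    predictions, and a seeded synthetic cohort generator with plantable
    driver-strength structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
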