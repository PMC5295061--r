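Package: leuflux
Title: Arteriovenous Leucine Tracer Kinetics Across the Hindlimb
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for primed-continuous stable-isotope infusion
    studies of limb protein turnover. Converts raw ion-ratio and assay
    measurements to tracer-to-tracee ratios and mole percent excess,
    identifies isotopic and concentration steady states on infusion time
    courses, computes plasma flow across the limb by p-aminohippurate
    indicator dilution, and partitions leucine disposal into protein
    synthesis, degradation, deposition, net transamination and oxidation
    with the two-pool arteriovenous tracer-balance model. Includes group
    statistics (pooled-variance t-tests, pooled SEM, Pearson correlation
    matrices) and a forward simulator of the full infusion protocol for
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
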