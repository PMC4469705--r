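Package: its2cbc
Title: ITS-2 Secondary-Structure DNA Barcoding and CBC-Based Species
    Delimitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structure-aware DNA barcoding of the nuclear ribosomal
    internal transcribed spacer 2 (ITS-2). Extracts the conserved
    barcode region from per-strain secondary structures (the 5.8S/LSU
    stem and Helices I-III), translates base pairs into the 1-8 number
    code, detects compensatory base changes (CBCs) and hemi-CBCs to
    delimit species, builds neighbor-joining distance phylogenies of the
    number-coded barcodes, screens query sequences against a reference
    panel by global identity with V4/V9 marker support, and fits
    exponential growth rates to derive a relative salinity-sensitivity
    statistic. Includes seeded simulators for barcode panels, growth
    curves and query sets so every stage can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
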