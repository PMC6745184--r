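Package: aqprofiler
Title: Aquaporin Family Annotation, Classification and Functional Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Annotation pipeline for plant aquaporin (major intrinsic
    protein) families. Computes physicochemical profiles (length, molecular
    weight, isoelectric point, hydropathy-based transmembrane segments),
    extracts the NPA motifs, aromatic/arginine (ar/R) selectivity filter,
    Froger's positions and the nine specificity-determining positions (SDPs)
    by alignment anchoring against function-known aquaporins, classifies
    queries into the PIP/TIP/NIP/SIP subfamilies with distance-based
    neighbor-joining phylogenetics, and predicts non-aqua substrate
    specificity (ammonia, boric acid, CO2, H2O2, silicic acid, urea) with a
    rule engine over published SDP patterns. Also includes qRT-PCR relative
    expression quantification (delta-Ct and delta-delta-Ct) and osmotic
    water permeability (Pf) estimation from oocyte swelling assays, plus
    synthetic-data generators providing ground-truth fixtures for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    seqinr,
    rtracklayer,
    optparse,
    withr
Config/testthat/edition: 3
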