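Package: cobakit
Title: Cobamide Producer Prediction from Genomes and Trait-Labelled
    Community Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies prokaryotic genomes and metagenome-assembled
    genomes (MAGs) into four cobamide-producer phenotypes (very likely,
    likely, possible, nonproducer) from profile-HMM marker-gene evidence,
    with contig-level false-positive screening and an aerobic/anaerobic
    route call.  Builds curated producer/nonproducer 16S rRNA reference
    sets from classified genomes, annotates amplicon OTUs against them by
    exact full-coverage matching, and tests whether producer taxa act as
    hubs in abundance-based co-occurrence networks.  Ships a synthetic
    fixture generator with known ground truth so the whole pipeline runs
    and validates without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    igraph,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
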