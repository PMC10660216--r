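Package: metathermo
Title: Environmental Temperature Prediction from Metagenomic Amino-Acid
    Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A metagenomic thermometer: predicts the temperature of an
    environment from shotgun metagenomic reads by extracting candidate
    coding fragments in all six reading frames, resolving one coding frame
    per read by codon-usage likelihood, pooling the amino-acid composition
    of the translated fragments, and applying the linear relation between
    optimal growth temperature and the proteome fraction of the seven
    residues Ile, Val, Tyr, Trp, Arg, Glu and Leu (F_IVYWREL).  Also
    provides a per-genome optimal-growth-temperature predictor for protein
    FASTA files, a fixed-period sinusoid fitter with phase-lag estimation
    for seasonal temperature series, and a synthetic-metagenome generator
    with prescribed amino-acid composition so the whole pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
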