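Package: estlfq
Title: Label-Free Shotgun Proteomics Quantification for Organisms
    Without a Sequenced Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for label-free shotgun proteomics in non-model
    organisms. Builds a non-redundant protein search database from
    EST/unigene and protein collections (six-frame translation, stop-codon
    splitting, length filtering and 100%-identity redundancy removal with a
    full conversion table), filters peptide-spectrum matches with
    charge-dependent Xcorr thresholds and reversed-decoy FDR estimation,
    quantifies proteins by two independent label-free routes -- peak
    integration over retention-time-aligned m/z x RT frames (dMS) and
    unweighted spectral counting with a Poisson-Gamma Bayes factor (SC) --
    and classifies per-protein agreement between the two routes. A seeded
    synthetic-data generator produces every input kind with recorded
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
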