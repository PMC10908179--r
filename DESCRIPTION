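Package: foldback
Title: Fold-Back Structure Scanning and Library-Preparation Artifact
    Variant Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects imperfect inverted repeat sequences (IVS) and
    imperfect palindromic sequences (PS) in targeted reference regions,
    derives a potential mutation blacklist at their mismatch and gap
    sites, and filters variant calls against it. Such fold-back
    structures seed chimeric template formation during sonication or
    enzymatic fragmentation library preparation (the PDSM model:
    pairing of partial single strands derived from a similar molecule),
    which induces low-frequency artifact SNVs and indels at
    imperfect-pairing positions. A simulator generates synthetic
    references with planted structures, chimeric templates for both
    fragmentation chemistries, error-free PCR amplification and read
    sampling, plus a naive pileup caller, so the whole
    detect-blacklist-filter loop can be validated in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    vcfR,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
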