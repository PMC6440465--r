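Package: iddfam
Title: Comparative Analysis of Plant INDETERMINATE DOMAIN Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for comparative analysis of the
    INDETERMINATE DOMAIN (IDD) zinc-finger gene family in plant genomes:
    family identification by similarity prefilter and ID-domain assembly
    (four ordered zinc fingers, NLS and C-terminal motif annotation),
    ExPASy-style protein physicochemistry (molecular weight, isoelectric
    point, GRAVY), tandem/segmental duplication classification,
    Nei-Gojobori Ka/Ks with Jukes-Cantor correction and sliding-window
    selection-pressure profiles, simplified MCScanX-style microsynteny,
    promoter cis-acting element scanning, neighbor-joining grouping, and
    qPCR 2^-delta-delta-Ct relative expression. A synthetic-data generator
    with planted ground truth makes every stage testable without genome
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    withr
Config/testthat/edition: 3
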