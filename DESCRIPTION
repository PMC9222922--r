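Package: retrotraffic
Title: Retrogene Discovery, Synteny Dating, and Interchromosomal
    Gene-Traffic Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies retrogene/parental gene pairs in annotated genomes
    by protein alignment and intron-loss evidence, dates retroduplication
    events onto labeled phylogenetic stages with a synteny-based method,
    and tests the resulting interchromosomal gene traffic against a
    parameterized random-movement expectation (the out-of-the-X test).
    Also classifies sex-biased expression of retrogenes and their parents
    from reproductive-organ microarray/RNA-seq data and spermatogenesis
    stage profiles, and ships a synthetic-clade simulator with a
    ground-truth ledger so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
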