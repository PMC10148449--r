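Package: cnvflow
Title: SNP-Array CNV Calling, Signal Review and Case-Control Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end workflow for copy-number-variant (CNV) case-control
    association from SNP-array intensity data. Simulates Illumina-style Log R
    Ratio / B-allele-frequency signal tracks with planted deletions and
    duplications, calls CNVs with a five-state hidden Markov model over copy
    number driven by LRR, BAF, inter-probe spacing and the population frequency
    of the B allele, applies sample-level quality filters (call rate, LRR
    standard deviation, large syndromic events), automates "review first"
    signal-level validation of every call against expected LRR shifts and BAF
    cluster structure, tests probe-level case-control carriage with Fisher's
    exact test, collapses significant probes into CNV regions, corrects for
    multiple testing (Bonferroni, Benjamini-Hochberg FDR, simpleM), and
    restricts results to a gene network of interest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
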