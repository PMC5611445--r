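Package: regelscreen
Title: Comparative Screening of UCP1 Upstream Regulatory Elements
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects, classifies, and maps the evolutionary gain and loss of
    the transcriptional regulatory elements upstream of the mammalian UCP1
    gene: the distal enhancer box, the putative regulatory region (PRR), the
    promoter CpG island, and basal promoter binding motifs. Provides windowed
    dot-plot homology screening with conserved-segment extraction, sliding
    window CpG-island detection under the observed/expected CpG criteria, a
    curated catalog of enhancer and promoter motifs with mutagenesis-derived
    critical cores, majority-rule consensus over intact-gene species, Dollo
    parsimony gain/loss mapping on a rooted species tree, and a phylogenetic
    sequence simulator with per-branch rate multipliers, indels, and element
    deletions that emits ground truth for every downstream stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
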