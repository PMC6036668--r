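Package: htscan
Title: Detecting Horizontal Transfer of LINE Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting horizontal transfer (HT) of
    LINE retrotransposons (exemplified by BovB and L1 families) between
    divergent eukaryotic lineages. Mines TE copies from genome assemblies by
    seeded local alignment, builds per-species consensus/centroid
    representatives, clusters copies across species with greedy-centroid and
    single-linkage engines, flags clusters spanning divergent taxonomic ranks,
    and validates candidates with flank-contrast, reciprocal-best-hit and
    phylogenetic-discordance tests. Includes Kimura two-parameter divergence
    landscapes and a ground-truthed simulator of TE evolution along a species
    tree (amplification bursts, decay by segmental deletion, planted
    cross-lineage transfer events) so every stage is testable without external
    genome downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    tibble,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
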