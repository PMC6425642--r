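Package: phageminer
Title: Phage Contig Mining and Analysis for Metagenomic Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies bacteriophage contigs in mixed metagenomic
    assemblies and analyses the recovered phage community. Labels
    contigs against paired phageome assemblies, extracts per-contig
    annotation features, trains and applies a random-forest phage
    classifier with abundance-weighted evaluation, computes virus
    quotients for phage orthologous groups, predicts phage-host links
    from CRISPR spacers, assigns phage taxonomy with a bootstrapped
    naive-Bayes 8-mer classifier, and compares phage functional
    profiles and diversity between sample groups. A seeded simulator
    of paired metagenome/phageome studies makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    Biostrings,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
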