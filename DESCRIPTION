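Package: amylatlas
Title: Genus-Wide Mining of Secreted Amylases and Amylase-Inhibitor Gene
    Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for comparative mining of secreted
    GH13 amylases and amylase-inhibitor biosynthetic gene clusters (BGCs)
    across bacterial genome cohorts, modelled on Streptomyces. Provides
    strict readers and writers for annotation tables, FASTA alignments and
    Newick trees; a secretome filter reducing CAZyme calls to clade-typed
    secreted amylases; midpoint rooting, tree-cut clade extraction and
    consensus-nearest representative selection; required/optional-gene
    cluster detection with flanking-amylase counting; exact and rank-based
    association statistics with effect sizes (Fisher's exact test,
    Mann-Whitney U with rank-biserial r, chi-square with phi,
    Benjamini-Hochberg and Bonferroni corrections); a column-wise
    residue-enrichment scan over multiple sequence alignments with
    reference-coordinate substitution labels; and a seeded synthetic-cohort
    generator with planted associations for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
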