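Package: anipan
Title: Isolate Genome Resource Analytics: ANI Taxonomy, Quality Gating,
    Assembly Splitting and Pan-Genome Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing collections of cultivated
    bacterial isolate genomes. Implements tetranucleotide-signature
    prefiltered taxonomy assignment by fragment-based average nucleotide
    identity (ANI) and percentage of conserved proteins (POCP), draft-genome
    quality gating against the Human Microbiome Project criteria with
    single-copy-marker completeness and contamination, density-based
    splitting of multi-genome isolate assemblies in GC-by-depth space with
    reference-guided scaffold rescue, 95 percent-ANI species clustering with
    N50-based representative selection, and pan-genome core/accessory/unique
    partitioning with Heaps-law openness fitting, exact Wilcoxon signed-rank
    functional enrichment and boolean pathway-completeness calls. A
    synthetic-data module generates genomes, mixed assemblies and
    pan-genome collections with known ground truth so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
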