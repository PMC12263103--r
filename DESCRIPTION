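Package: derephits
Title: Genome-Level Dereplication of Gene Cluster Mining Hit Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Removes genomic redundancy from gene cluster mining hit sets
    produced by cblaster-style searches. Hits are grouped by dereplicating
    their host genome assemblies with a k-mer containment estimator of
    average nucleotide identity (ANI) and a greedy representative-selection
    rule driven by redundancy-graph connectedness, assembly N50 and total
    length. Discarded hits are recovered when their gene-cluster content
    (homolog-count vector) differs from the representative's, or when their
    homology score is a z-score outlier within their subgroup. Includes a
    synthetic genome and session generator with controlled pairwise
    divergence so the whole workflow is testable offline, and writes the
    seven standard output text files consumed by downstream comparative
    genomics tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Biostrings,
    optparse,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
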