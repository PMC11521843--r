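Package: epletatlas
Title: Eplet-Based HLA Amino-Acid Atlases, Disparity Graphs and Mismatch Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates antibody-confirmed HLA eplets into per-allele polymorphic
    amino-acid profiles, computes pairwise Hamming distances between alleles in
    differential amino-acid space, builds 1-nearest-neighbour disparity graphs per
    allele group with cross-reactive augmentation, summarises cross-reactivity at
    group and locus level, and counts antigen/allele and eplet mismatches for
    donor-recipient pairs. Includes a synthetic-registry generator with planted
    monomorphic clusters and cross-reactive alleles for end-to-end validation, and
    a command-line interface for atlas export, motif plots, graph export, summary
    tables and mismatch reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    ggplot2,
    optparse,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
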