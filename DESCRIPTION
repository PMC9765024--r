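Package: siteseer
Title: Transfer and Visualization of Experimentally Determined Functional
    Residues in Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a database of experimentally determined functional
    residues from Swiss-Prot flat-file feature tables and BioLiP-style
    binding/active-site records, transfers those sites onto query proteins
    through pairwise local alignments with per-residue conservation calls,
    and visualizes selected sites across a protein family on a
    midpoint-rooted phylogenetic tree in full and compact SVG views.
    Includes readers and writers for FASTA, Clustal and Stockholm
    alignments and Newick trees, a progressive multiple aligner and
    neighbor-joining tree builder for desk-scale families, a protein
    motif/pattern search, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
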