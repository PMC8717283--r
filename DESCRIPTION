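Package: tastemine
Title: Mining and Evolutionary Analysis of Vertebrate Taste Receptor Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for comparative genomics of
    intronless G-protein-coupled taste receptor families (Tas1r umami/sweet and
    Tas2r bitter receptors). Mines receptor genes from genome assemblies by
    translated six-frame homology search with hit filtering, merging and flank
    extension; classifies gene models as intact, partial or pseudogenes from
    open-reading-frame integrity, premature stops, frameshifts and a
    Kyte-Doolittle seven-transmembrane screen; distinguishes true gene loss from
    assembly gaps by flanking-marker synteny; reconstructs duplication and loss
    trajectories by LCA gene-tree/species-tree reconciliation; estimates
    selective pressure with Nei-Gojobori dN/dS and a binomial site-wise
    selection scan; and predicts umami and sweet function from Tas1r
    heterodimer logic. A synthetic-data module generates genomes with planted
    receptor genes, birth-death gene-family histories and codon alignments
    under site-wise selection, with recorded ground truth, so every stage is
    validated against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
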