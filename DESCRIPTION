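Package: cgrmap
Title: Molecular Distance Maps from Chaos Game Representations of DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Alignment-free comparison and visualization of DNA sequences.
    Each sequence is encoded as a Chaos Game Representation (CGR) raster in
    which every pixel marks the occurrence of one k-mer; pairs of CGR images
    are compared with the structural dissimilarity index (DSSIM = 1 - SSIM);
    and the resulting distance matrix is projected to a low-dimensional
    Molecular Distance Map by classical (Torgerson) multidimensional scaling
    with Kruskal Stress-1 quality reporting. Includes FASTA input/output,
    trinucleotide-frequency-preserving sequence randomization via Eulerian
    paths on the dinucleotide de Bruijn multigraph, a Markov-family sequence
    simulator, and an end-to-end pipeline with run manifests, distance-matrix
    export (TSV and PHYLIP) and map plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
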