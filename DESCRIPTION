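Package: fishcoder
Title: Probe Design, Simulation and Combinatorial Decoding for Sequential FISH
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico toolkit for combinatorial sequential fluorescence
    in situ hybridization (seqFISH-style) experiments. Designs encoding
    probes from transcript sequences under length, GC and k-mer off-target
    rules; assigns genes unordered four-pseudocolor barcodes over a
    rounds-by-channels acquisition space; simulates multi-round image
    stacks with known ground truth (Gaussian point-spread, rigid drift,
    illumination bias, shot and read noise, dropout, spurious spots);
    recovers transcripts through registration, tophat background
    correction, total-variation denoising, Richardson-Lucy deconvolution,
    local-maxima spot calling with radial-center subpixel refinement, and
    nearest-neighbour barcode decoding with minimum-distance ambiguity
    resolution; and emits a gene-by-cell count matrix after watershed
    nucleus segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    Biostrings,
    EBImage,
    SummarizedExperiment,
    S4Vectors,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
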