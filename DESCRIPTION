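Package: linkbin
Title: Barcode-Aware Read Binning for Linked-Read Metagenome Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bins co-barcoded short reads from linked-read metagenomic
    sequencing (stLFR, TELL-Seq, 10x Genomics) or virtually barcoded hybrid
    sequencing so that each bin can be assembled independently. Per-barcode
    features combine a global 15-mer abundance histogram with tetranucleotide
    frequencies; a variational autoencoder trained with abundance-balanced
    weighted sampling embeds barcodes into a latent space that is clustered
    with random-projection-hash initialised k-means. Companion tools
    reconstruct physical DNA fragments from barcoded alignments, assign
    virtual barcodes from short-read-to-long-read alignments, partition reads
    by contig depth for low-abundance reassembly, classify MAG quality tiers,
    and simulate linked-read communities with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
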