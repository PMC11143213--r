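# Shared fixtures, memoised across test files so expensive simulations and
# the embedder training run once per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# majority source genome per barcode (multi-fragment barcodes can mix genomes)
barcode_truth <- function(truth_pairs) {
  truth_pairs |>
    dplyr::summarise(
      genome = names(which.max(table(genome))),
      .by = "barcode"
    )
}

# The 3-genome study community (package defaults: abundances 100/30/10,
# distinct compositional signatures) at full test scale, with features.
study_community <- function(n_barcodes = 3000, seed = 1L) {
  memo(paste0("community_", n_barcodes, "_", seed), function() {
    cc <- community_config()
    genomes <- simulate_genomes(cc, seed = seed)
    sim <- simulate_linked_reads(genomes,
                                 linked_read_config(seed = seed + 100L),
                                 n_barcodes = n_barcodes)
    grouping <- group_by_barcode(sim$reads)
    table <- build_kmer_table(sim$reads)
    features <- barcode_features(grouping$groups, table)
    list(
      config = cc, genomes = genomes, sim = sim, grouping = grouping,
      table = table, features = features,
      truth = barcode_truth(sim$truth_pairs)
    )
  })
}

# Trained embedder + latent means for the study community: the "small VAE"
# (two 128-unit hidden layers, <= 50 epochs) used throughout the latent tests.
study_embedding <- function(n_barcodes = 3000, seed = 1L) {
  memo(paste0("embedding_", n_barcodes, "_", seed), function() {
    com <- study_community(n_barcodes, seed)
    embedder <- train_embedder(
      com$features,
      embedder_config(hidden_sizes = c(128, 128), max_epochs = 50,
                      patience = 10, seed = seed)
    )
    list(embedder = embedder, mu = embed_barcodes(embedder, com$features))
  })
}

# A small flat community for fast statistical fixtures (fragment collisions
# on one genome would bias N_F/B recovery; many equal genomes keep the
# same-genome collision probability negligible).
flat_community <- function(seed = 1L) {
  memo(paste0("flat_", seed), function() {
    cc <- community_config(n_genomes = 20, genome_length = 2e5,
                           abundances = rep(1, 20),
                           gc_contents = seq(0.35, 0.6, length.out = 20),
                           tnf_bias_sd = 0.3)
    simulate_genomes(cc, seed = seed)
  })
}

random_dna <- function(n, len, seed = NULL) {
  draw <- function() {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

make_reads <- function(seq1, seq2 = seq1, barcode = "1_2_3",
                       id_prefix = "r") {
  n <- length(seq1)
  tibble::tibble(
    read_id = paste0(id_prefix, seq_len(n)),
    seq1 = seq1, qual1 = strrep("I", nchar(seq1)),
    seq2 = seq2, qual2 = strrep("I", nchar(seq2)),
    barcode = rep_len(barcode, n),
    technology = "stlfr"
  )
}

# random depth-partition instance shared by the depth and acceptance tests
fuzzed_partition_case <- function(n_pairs = 100, n_contigs = 8) {
  contigs <- paste0("c", seq_len(n_contigs))
  lengths <- tibble::tibble(contig = contigs,
                            length = sample(500:2000, n_contigs,
                                            replace = TRUE))
  n_aln <- rpois(1, n_pairs)
  aln <- tibble::tibble(
    read_id = sample(paste0("p", seq_len(n_pairs)), n_aln, replace = TRUE),
    contig = sample(contigs, n_aln, replace = TRUE),
    aligned_bases = sample(50:150, n_aln, replace = TRUE),
    primary = TRUE
  )
  list(ids = paste0("p", seq_len(n_pairs)), aln = aln, lengths = lengths)
}

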