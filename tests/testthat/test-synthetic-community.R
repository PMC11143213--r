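test_that("genome simulation is reproducible and hits target GC", {
  cc <- community_config(n_genomes = 1, genome_length = 1000,
                         abundances = 1, gc_contents = 0.5)
  g1 <- simulate_genomes(cc, seed = 3)
  g2 <- simulate_genomes(cc, seed = 3)
  expect_identical(g1, g2)
  expect_equal(nchar(g1$seq), 1000)

  cc2 <- community_config(n_genomes = 1, genome_length = 2e5,
                          abundances = 1, gc_contents = 0.30)
  g <- simulate_genomes(cc2, seed = 5)
  expect_gte(g$gc_realized, 0.28)
  expect_lte(g$gc_realized, 0.32)
})

test_that("linked-read simulation is reproducible with a consistent truth table", {
  genomes <- simulate_genomes(
    community_config(n_genomes = 2, genome_length = 3e4,
                     abundances = c(0.7, 0.3), gc_contents = c(0.4, 0.6)),
    seed = 2
  )
  lrc <- linked_read_config(seed = 9)
  a <- simulate_linked_reads(genomes, lrc, n_barcodes = 40)
  b <- simulate_linked_reads(genomes, lrc, n_barcodes = 40)
  expect_identical(a, b)
  # truth covers every emitted pair exactly once; no orphan rows
  expect_setequal(a$truth_pairs$read_id, a$reads$read_id)
  expect_equal(anyDuplicated(a$truth_pairs$read_id), 0)
  expect_setequal(a$truth_pairs$fragment_id, a$truth_fragments$fragment_id)
  # pair coordinates lie inside their fragment, fragments inside their genome
  j <- dplyr::inner_join(a$truth_pairs, a$truth_fragments,
                         by = "fragment_id", suffix = c("", ".f"))
  expect_true(all(j$start1 >= j$start & j$end2 <= j$end))
  glen <- setNames(genomes$length, genomes$genome)
  expect_true(all(a$truth_fragments$end <= unname(glen[a$truth_fragments$genome])))
})

test_that("degenerate fragment mean gives exactly one fragment per barcode", {
  genomes <- simulate_genomes(
    community_config(n_genomes = 1, genome_length = 5e4, abundances = 1,
                     gc_contents = 0.5),
    seed = 1
  )
  sim <- simulate_linked_reads(
    genomes, linked_read_config(mean_fragments_per_barcode = 1, seed = 4),
    n_barcodes = 300
  )
  per_bc <- dplyr::count(sim$truth_fragments, barcode)
  expect_true(all(per_bc$n == 1))
})

test_that("error-free reads are exact genome substrings", {
  genomes <- simulate_genomes(
    community_config(n_genomes = 1, genome_length = 5e4, abundances = 1,
                     gc_contents = 0.45),
    seed = 6
  )
  sim <- simulate_linked_reads(
    genomes, linked_read_config(substitution_error_rate = 0, seed = 7),
    n_barcodes = 20
  )
  j <- dplyr::inner_join(sim$reads, sim$truth_pairs, by = "read_id")
  m1 <- substring(genomes$seq, j$start1 + 1, j$end1)
  m2 <- substring(genomes$seq, j$start2 + 1, j$end2)
  expect_equal(j$seq1, m1)
  expect_equal(j$seq2, revcomp_chr(m2))
})

test_that("read origins follow abundance after length correction", {
  genomes <- simulate_genomes(
    community_config(n_genomes = 2, genome_length = 5e4,
                     abundances = c(0.9, 0.1), gc_contents = 0.5),
    seed = 8
  )
  sim <- simulate_linked_reads(
    genomes,
    linked_read_config(pairs_per_fragment_mean = 8,
                       fragment_length_mean = 5000,
                       fragment_length_sd = 500, seed = 9),
    n_barcodes = 17000, sequences = FALSE
  )
  expect_gte(nrow(sim$truth_pairs), 1e5)
  frac <- prop.table(table(sim$truth_pairs$genome))
  # equal lengths, so the length correction is the identity
  expect_lt(abs(frac[["genome1"]] - 0.9), 0.01)
  expect_lt(abs(frac[["genome2"]] - 0.1), 0.01)
})

test_that("long-read simulation is reproducible, exact at zero error, empty at n = 0", {
  genomes <- simulate_genomes(
    community_config(n_genomes = 2, genome_length = 4e4,
                     abundances = c(0.6, 0.4), gc_contents = c(0.4, 0.55)),
    seed = 3
  )
  a <- simulate_long_reads(genomes, 50, length_mean = 5000, error_rate = 0,
                           seed = 2)
  b <- simulate_long_reads(genomes, 50, length_mean = 5000, error_rate = 0,
                           seed = 2)
  expect_identical(a, b)
  j <- dplyr::inner_join(a$reads, a$truth, by = "read_id")
  gseq <- setNames(genomes$seq, genomes$genome)
  expect_equal(j$seq, unname(substring(gseq[j$genome], j$start + 1, j$end)))

  empty <- simulate_long_reads(genomes, 0, seed = 1)
  expect_equal(nrow(empty$reads), 0)
  expect_equal(nrow(empty$truth), 0)
})
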