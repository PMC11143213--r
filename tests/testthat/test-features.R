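test_that("global k-mer table counts windows canonically and skips N", {
  cfg <- feature_config()
  # 20-base homopolymer has 6 windows of one 15-mer
  tab <- build_kmer_table(strrep("A", 20), cfg)
  expect_equal(length(tab$code), 1)
  expect_equal(tab$count, 6)
  # a read plus its reverse complement doubles the table of the read alone
  r <- random_dna(1, 60, seed = 10)
  t1 <- build_kmer_table(r, cfg)
  t2 <- build_kmer_table(c(r, revcomp_chr(r)), cfg)
  expect_equal(t2$code, t1$code)
  expect_equal(t2$count, 2 * t1$count)
  # windows containing N are not counted
  tn <- build_kmer_table(paste0(strrep("A", 10), "N", strrep("A", 10)), cfg)
  expect_equal(sum(tn$count), 0)
})

test_that("global table matches the enumeration oracle", {
  seqs <- c(random_dna(4, 40, seed = 11), "ACGTNNACGTACGTACGTAC")
  tab <- build_kmer_table(seqs, feature_config())
  oracle <- oracle_kmer_table(seqs, 15)
  expect_equal(sum(tab$count), sum(oracle))
  expect_equal(length(tab$code), length(oracle))
  expect_equal(sort(kmer_frequency(tab, names(oracle))),
               sort(as.numeric(oracle)))
})

test_that("abundance histogram bins by global frequency with a hard cap", {
  cfg <- feature_config()
  probe <- "ACGTGATTACAGCTA"  # one 15-mer, not self-reverse-complementary
  build_case <- function(global_copies) {
    dataset <- c(rep(probe, global_copies), random_dna(3, 40, seed = 12))
    tab <- build_kmer_table(dataset, cfg)
    groups <- group_by_barcode(make_reads(probe, probe), min_total_bases = 1)
    barcode_features(groups$groups, tab, cfg)
  }
  f25 <- build_case(25)  # global frequency 25 -> bin 3 covers (20, 30]
  xa <- f25$x_a[[1]]
  expect_equal(which(xa > 0), 3)
  expect_equal(sum(xa), 1)

  f4000 <- build_case(4000)   # frequency 4000 -> retained in bin 400
  expect_equal(which(f4000$x_a[[1]] > 0), 400)
  f4001 <- build_case(4001)   # frequency 4001 -> discarded, all-zero record
  expect_equal(sum(f4001$x_a[[1]]), 0)
  expect_true(f4001$flagged)
})

test_that("feature dimensions and normalisation are invariant", {
  com <- study_community(300, seed = 1)
  f <- com$features
  expect_true(all(purrr::map_int(f$x_a, length) == 400L))
  expect_true(all(purrr::map_int(f$x_t, length) == 136L))
  ok <- !f$flagged
  expect_true(all(abs(purrr::map_dbl(f$x_a[ok], sum) - 1) < 1e-9))
  expect_true(all(abs(purrr::map_dbl(f$x_t, sum) - 1) < 1e-9))
  fm <- feature_matrix(f)
  expect_equal(ncol(fm$x), 536)
})

test_that("features are invariant to read order and strand", {
  seqs <- random_dna(6, 50, seed = 13)
  dataset_tab <- build_kmer_table(c(seqs, random_dna(5, 50, seed = 14)),
                                  feature_config())
  as_group <- function(ss) {
    group_by_barcode(make_reads(ss[seq(1, 5, 2)], ss[seq(2, 6, 2)]),
                     min_total_bases = 1)$groups
  }
  base <- barcode_features(as_group(seqs), dataset_tab)
  shuffled <- barcode_features(as_group(seqs[c(5, 6, 3, 4, 1, 2)]),
                               dataset_tab)
  flipped <- barcode_features(as_group(revcomp_chr(seqs)), dataset_tab)
  expect_equal(shuffled$x_a, base$x_a)
  expect_equal(shuffled$x_t, base$x_t)
  expect_equal(flipped$x_a, base$x_a)
  expect_equal(flipped$x_t, base$x_t)
})

test_that("X_A and X_T match the naive window-enumeration oracle", {
  withr::with_seed(15, {
    for (rep in 1:3) {
      group_seqs <- random_dna(sample(2:10, 1), 45)
      other <- random_dna(6, 45)
      all_seqs <- c(group_seqs, other)
      tab <- build_kmer_table(all_seqs, feature_config())
      # build a one-barcode group holding exactly group_seqs ("N" padding
      # contributes no windows)
      n <- length(group_seqs)
      half <- ceiling(n / 2)
      padded <- c(group_seqs, rep("N", 2 * half - n))
      groups <- group_by_barcode(
        make_reads(padded[seq_len(half)], padded[half + seq_len(half)]),
        min_total_bases = 1
      )
      got <- barcode_features(groups$groups, tab, feature_config())
      want <- oracle_features(group_seqs, all_seqs)
      expect_equal(got$x_a[[1]], want$x_a, tolerance = 1e-12)
      expect_equal(got$x_t[[1]], want$x_t, tolerance = 1e-12)
    }
  })
})

test_that("canonical tetramer classes collapse reverse complements into 136 slots", {
  slots <- linkbin:::cpp_tnf_slot_table()
  expect_equal(length(unique(slots)), 136)
  code <- function(s) {
    sum(c(A = 0, C = 1, G = 2, T = 3)[strsplit(s, "")[[1]]] * 4^(3:0))
  }
  expect_equal(slots[code("AAAA") + 1], slots[code("TTTT") + 1])
  expect_equal(slots[code("ACGT") + 1], slots[code("ACGT") + 1])
  for (km in c("GATC", "TTAG", "CCCC")) {
    expect_equal(slots[code(km) + 1], slots[code(revcomp_chr(km)) + 1])
  }
})

test_that("sampling weight is the squared histogram peak", {
  expect_equal(sampling_weight(c(0.5, 0.3, 0.2)), 0.25)
  expect_equal(sampling_weight(rep(1 / 400, 400)), (1 / 400)^2)
  expect_equal(sampling_weight(c(rep(0, 399), 1)), 1)
  expect_equal(sampling_weight(numeric(400)), 0)
})

test_that("low-abundance barcodes carry larger histogram peaks", {
  com <- study_community(3000, seed = 1)
  w <- com$features |>
    dplyr::inner_join(com$truth, by = "barcode") |>
    dplyr::summarise(peak = mean(purrr::map_dbl(x_a, max)), .by = "genome")
  # genome3 is the lowest-abundance genome, genome1 the highest
  expect_gt(w$peak[w$genome == "genome3"], w$peak[w$genome == "genome1"])
})
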