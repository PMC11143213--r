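aln <- function(barcode, ref, start, end, read_id) {
  tibble::tibble(barcode = barcode, ref = ref, start = start, end = end,
                 read_id = read_id)
}

test_that("fragment chaining applies the gap, pair-count and length rules", {
  a <- aln("b1", "c1", c(1000, 5000, 20000), c(1100, 5100, 20100),
           c("r1", "r2", "r3"))
  frags <- reconstruct_fragments(a)
  # two candidates; [1000, 5100] kept (2 pairs, 4100 bp), the singleton dropped
  expect_equal(nrow(frags), 1)
  expect_equal(frags$start, 1000)
  expect_equal(frags$end, 5100)
  expect_equal(frags$read_pair_count, 2L)

  # two pairs 900 bp apart spanning 950 bp total: below the 1 kb floor
  short <- aln("b1", "c1", c(0, 900), c(100, 950), c("r1", "r2"))
  expect_equal(nrow(reconstruct_fragments(short)), 0)

  empty <- aln(character(), character(), numeric(), numeric(), character())
  expect_equal(nrow(reconstruct_fragments(empty)), 0)
})

test_that("unsorted alignments are rejected", {
  bad <- aln("b1", "c1", c(5000, 1000), c(5100, 1100), c("r1", "r2"))
  expect_error(reconstruct_fragments(bad), "sorted")
})

test_that("chaining matches the exhaustive oracle on fuzzed inputs", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      n <- sample(3:20, 1)
      a <- tibble::tibble(
        barcode = sample(c("b1", "b2"), n, replace = TRUE),
        ref = sample(c("c1", "c2"), n, replace = TRUE),
        start = sample(0:40000, n),
        read_id = paste0("r", seq_len(n))
      )
      a$end <- a$start + sample(80:300, n, replace = TRUE)
      a <- dplyr::arrange(a, ref, start)
      got <- reconstruct_fragments(a) |> dplyr::arrange(barcode, ref, start)
      want <- oracle_fragments(a)
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        want <- dplyr::arrange(want, barcode, ref, start)
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        expect_equal(got$read_pair_count, want$read_pair_count)
      }
    }
  })
})

test_that("barcode statistics are exact on hand counts", {
  one_each <- tibble::tibble(barcode = c("a", "b", "c"))
  s <- barcode_stats(one_each)
  expect_equal(s$nf_per_b, 1)
  expect_equal(s$fraction_multi_fragment, 0)

  mixed <- tibble::tibble(barcode = rep(c("a", "b", "c"), times = c(1, 2, 3)))
  s2 <- barcode_stats(mixed)
  expect_equal(s2$nf_per_b, 2)
  expect_equal(s2$fraction_multi_fragment, 2 / 3)

  expect_error(barcode_stats(mixed[0, ]), "no fragments")
})

test_that("simulator round-trip recovers fragment counts and boundaries", {
  genomes <- flat_community(seed = 1)
  lrc <- linked_read_config(
    mean_fragments_per_barcode = 4.26, fragment_length_mean = 5000,
    fragment_length_sd = 1000, pairs_per_fragment_mean = 8,
    substitution_error_rate = 0, seed = 41
  )
  sim <- simulate_linked_reads(genomes, lrc, n_barcodes = 10000,
                               sequences = FALSE)
  frags <- reconstruct_fragments(truth_alignments(sim$truth_pairs))
  s <- barcode_stats(frags)
  expect_lt(abs(s$nf_per_b - 4.26), 0.1)
  # on single-fragment barcodes the reconstruction must sit inside the truth
  # interval (reads sample the fragment interior) and approach its ends
  single_truth <- sim$truth_fragments |>
    dplyr::filter(dplyr::n() == 1, .by = "barcode")
  single_got <- frags |> dplyr::filter(dplyr::n() == 1, .by = "barcode")
  j <- dplyr::inner_join(single_got, single_truth, by = "barcode",
                         suffix = c("", ".t"))
  expect_gt(nrow(j), 200)  # ~4% of barcodes are single-fragment at N_F/B 4.26
  expect_true(all(j$ref == j$genome))
  expect_true(all(j$start >= j$start.t & j$end <= j$end.t))
  expect_true(all(j$read_pair_count <= j$n_pairs))
  # median slack at each boundary is a small fraction of the fragment length
  expect_lt(median(j$start - j$start.t), lrc$fragment_length_mean / 5)
  expect_lt(median(j$end.t - j$end), lrc$fragment_length_mean / 5)
})

test_that("virtual barcodes follow the 60 bp filter and seeded tie-break", {
  a <- tibble::tibble(
    read_id = c("p1", "p2", "p3", "p3"),
    long_read = c("L1", "L9", "L1", "L2"),
    aligned_bases = c(80, 50, 80, 70)
  )
  got <- assign_virtual_barcodes(a, seed = 1)
  expect_equal(got$barcode[got$read_id == "p1"], "L1")   # single survivor
  expect_true(is.na(got$barcode[got$read_id == "p2"]))   # below 60 bp
  expect_true(got$barcode[got$read_id == "p3"] %in% c("L1", "L2"))
  expect_equal(nrow(got), 3)

  # exactly 60 aligned bases survives the filter
  keep60 <- assign_virtual_barcodes(
    tibble::tibble(read_id = "p", long_read = "L5", aligned_bases = 60)
  )
  expect_equal(keep60$barcode, "L5")
})

test_that("ambiguous pairs are split evenly across candidate long reads", {
  picks <- vapply(1:4000, function(s) {
    a <- tibble::tibble(read_id = "p", long_read = c("L1", "L2"),
                        aligned_bases = c(80, 70))
    assign_virtual_barcodes(a, seed = s)$barcode
  }, character(1))
  expect_lt(abs(mean(picks == "L1") - 0.5), 0.02)
})

test_that("virtual assignment is order-invariant and reproducible", {
  withr::with_seed(32, {
    a <- tibble::tibble(
      read_id = sample(paste0("p", 1:50), 200, replace = TRUE),
      long_read = sample(paste0("L", 1:8), 200, replace = TRUE),
      aligned_bases = sample(30:200, 200, replace = TRUE)
    )
  })
  x <- assign_virtual_barcodes(a, seed = 9)
  y <- assign_virtual_barcodes(a[sample(nrow(a)), ], seed = 9)
  expect_identical(x, y)
})

test_that("virtual barcodes attach to read tables", {
  reads <- make_reads(random_dna(3, 50, seed = 33), barcode = "old")
  asg <- tibble::tibble(read_id = reads$read_id,
                        barcode = c("L1", NA, "L2"))
  out <- apply_virtual_barcodes(reads, asg)
  expect_equal(out$barcode, c("L1", NA, "L2"))
  expect_true(all(out$technology == "virtual"))
})
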