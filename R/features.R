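#' Feature extraction parameters
#'
#' Per-barcode features combine a histogram of global 15-mer frequencies
#' (X_A, an abundance proxy: 400 bins of width 10 covering frequencies 1–4000,
#' higher frequencies discarded as repeats) with canonical tetranucleotide
#' frequencies (X_T, 136 reverse-complement-collapsed classes). Both are
#' L1-normalised and concatenated into a 536-dimensional embedding input.
#'
#' @param kmer_size Odd k for the abundance k-mers (default 15).
#' @param max_kmer_frequency Global-frequency cap; k-mers above it are
#'   discarded (default 4000).
#' @param bin_width Histogram bin width (default 10); bin i covers
#'   frequencies in `(10i - 10, 10i]`.
#' @param canonical Use strand-collapsed k-mers for the global table and
#'   histogram lookup (default `TRUE`; reads arrive from both strands).
#'
#' @return A `feature_config` list; `n_bins` is derived as
#'   `max_kmer_frequency / bin_width`.
#' @export
feature_config <- function(kmer_size = 15, max_kmer_frequency = 4000,
                           bin_width = 10, canonical = TRUE) {
  stopifnot(kmer_size %% 2 == 1, kmer_size >= 3, kmer_size <= 31,
            max_kmer_frequency %% bin_width == 0)
  structure(
    list(
      kmer_size = as.integer(kmer_size),
      max_kmer_frequency = as.integer(max_kmer_frequency),
      bin_width = as.integer(bin_width),
      n_bins = as.integer(max_kmer_frequency / bin_width),
      tnf_k = 4L,
      n_tnf = 136L,
      pseudo = 1e-9,
      canonical = isTRUE(canonical)
    ),
    class = "feature_config"
  )
}

group_sequences <- function(groups) {
  purrr::map(groups$pairs, function(p) c(rbind(p$seq1, p$seq2)))
}

#' Build the global k-mer frequency table
#'
#' Counts every k-mer window (windows containing N are skipped) over the whole
#' dataset, collapsing each window with its reverse complement when
#' `config$canonical` is set. Counts are exact.
#'
#' @param reads Read-pair tibble, or a character vector of sequences.
#' @param config A [feature_config()].
#'
#' @return A `kmer_table` object (sorted numeric codes + counts).
#' @export
build_kmer_table <- function(reads, config = feature_config()) {
  seqs <- if (is.character(reads)) reads else c(rbind(reads$seq1, reads$seq2))
  if (length(seqs) == 0) abort("no reads supplied")
  if (!config$canonical) {
    tab <- cpp_count_plain_kmers(seqs, config$kmer_size)
  } else {
    tab <- cpp_count_canonical_kmers(seqs, config$kmer_size)
  }
  structure(
    list(code = tab$code, count = tab$count, k = config$kmer_size,
         canonical = config$canonical),
    class = "kmer_table"
  )
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("<kmer_table> k =", x$k, "|", length(x$code), "distinct",
      if (x$canonical) "canonical" else "plain", "k-mers | total count",
      format(sum(x$count), big.mark = ","), "\n")
  invisible(x)
}

#' Look up global frequencies of k-mers
#'
#' @param table A `kmer_table`.
#' @param kmers Character vector of k-mers.
#' @return Numeric vector of global counts (0 when unseen).
#' @export
kmer_frequency <- function(table, kmers) {
  codes <- cpp_encode_kmers(kmers, table$k, table$canonical)
  i <- findInterval(codes, table$code)
  out <- numeric(length(kmers))
  hit <- i > 0 & table$code[pmax(i, 1)] == codes
  out[hit] <- table$count[i[hit]]
  out[is.na(codes)] <- NA_real_
  out
}

l1_normalise <- function(v) {
  s <- sum(v)
  if (s > 0) v / s else v
}

#' Extract per-barcode features
#'
#' For every barcode group computes the abundance histogram `x_a` (each k-mer
#' window with global frequency f in `(0, max]` increments bin `ceiling(f /
#' bin_width)`; windows above the cap are discarded), the tetranucleotide
#' vector `x_t`, both L1-normalised, and the sampling weight `max(x_a)^2`
#' used to balance embedder training across abundances. Groups whose every
#' k-mer is discarded yield an all-zero `x_a` and are flagged
#' (`flagged = TRUE`) for exclusion from training.
#'
#' @param groups `groups` tibble from [group_by_barcode()].
#' @param table `kmer_table` from [build_kmer_table()] over the same dataset.
#' @param config A [feature_config()].
#'
#' @return Tibble with `barcode`, list-columns `x_a` (length
#'   `config$n_bins`) and `x_t` (length 136), `weight`, `flagged`.
#' @export
barcode_features <- function(groups, table, config = feature_config()) {
  stopifnot(inherits(table, "kmer_table"), table$k == config$kmer_size)
  feats <- purrr::map(group_sequences(groups), function(seqs) {
    counts <- cpp_barcode_feature_counts(
      seqs, table$code, table$count, config$kmer_size,
      config$max_kmer_frequency, config$bin_width, config$n_bins
    )
    list(x_a = l1_normalise(counts$hist), x_t = l1_normalise(counts$tnf))
  })
  x_a <- purrr::map(feats, "x_a")
  tibble(
    barcode = groups$barcode,
    x_a = x_a,
    x_t = purrr::map(feats, "x_t"),
    weight = sampling_weight(x_a),
    flagged = purrr::map_lgl(x_a, ~ sum(.x) == 0)
  )
}

#' Abundance-balancing sampling weight
#'
#' The peak of the k-mer frequency histogram is larger for barcodes from
#' low-abundance genomes (their true-k-mer frequency peak stacks onto the
#' error peak at low frequency), so `max(x_a)^2` up-weights rare genomes when
#' sampling training batches; the square sharpens the imbalance correction.
#'
#' @param x_a A normalised histogram vector or a list of them.
#' @return Numeric weight(s) in `[0, 1]`; all-zero histograms get weight 0.
#' @export
sampling_weight <- function(x_a) {
  if (is.list(x_a)) return(purrr::map_dbl(x_a, sampling_weight))
  if (length(x_a) == 0 || all(x_a == 0)) return(0)
  max(x_a)^2
}

#' Stack feature records into the embedder input matrix
#'
#' @param features Tibble from [barcode_features()].
#' @param drop_flagged Exclude flagged (all-zero histogram) records.
#' @return List with `x` (n x 536 matrix, rownames = barcodes), `dim_a`,
#'   `dim_t`, `weight`, and `barcode`.
#' @export
feature_matrix <- function(features, drop_flagged = TRUE) {
  if (drop_flagged) features <- dplyr::filter(features, !.data$flagged)
  if (nrow(features) == 0) abort("no usable feature records")
  dim_a <- length(features$x_a[[1]])
  dim_t <- length(features$x_t[[1]])
  x <- cbind(
    do.call(rbind, features$x_a),
    do.call(rbind, features$x_t)
  )
  rownames(x) <- features$barcode
  list(x = x, dim_a = dim_a, dim_t = dim_t,
       weight = features$weight, barcode = features$barcode)
}
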