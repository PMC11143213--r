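#' @section Synthetic communities:
#' The simulator emulates the fragment-per-barcode model of linked-read
#' sequencing: each barcode tags a small number of long DNA fragments, each
#' fragment sheds paired-end short reads, and the number of fragments per
#' barcode (N_F/B) controls barcode specificity.
#' @name linkbin-simulation
#' @keywords internal
NULL

BASES <- c("A", "C", "G", "T")

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Describe a synthetic community
#'
#' @param n_genomes Number of genomes.
#' @param genome_length Genome length(s) in bp (recycled).
#' @param abundances Relative abundances; normalised to sum to 1. The default
#'   100/30/10 mirrors a high/medium/low-abundance mix.
#' @param gc_contents Per-genome GC fraction in `[0, 1]` (recycled).
#' @param tnf_bias_sd Standard deviation of the per-genome log-tilt applied to
#'   Markov transition rows; gives each genome a distinct tetranucleotide
#'   signature. 0 disables compositional bias.
#'
#' @return A `community_config` list.
#' @export
community_config <- function(n_genomes = 3,
                             genome_length = 1e5,
                             abundances = c(100, 30, 10),
                             gc_contents = c(0.40, 0.50, 0.60),
                             tnf_bias_sd = 0.5) {
  stopifnot(n_genomes >= 1, all(genome_length > 0), all(abundances > 0))
  abundances <- rep_len(abundances, n_genomes)
  abundances <- abundances / sum(abundances)
  gc_contents <- rep_len(gc_contents, n_genomes)
  stopifnot(all(gc_contents > 0 & gc_contents < 1))
  structure(
    list(
      n_genomes = n_genomes,
      genome_length = rep_len(as.integer(genome_length), n_genomes),
      abundances = abundances,
      gc_contents = gc_contents,
      tnf_bias_sd = tnf_bias_sd
    ),
    class = "community_config"
  )
}

#' Parameters of the linked-read simulator
#'
#' @param mean_fragments_per_barcode Target N_F/B; fragment counts per barcode
#'   are `1 + Poisson(mean - 1)` so every barcode has at least one fragment
#'   while the mean is hit exactly. Default 1.54, the specificity of
#'   stLFR beads.
#' @param fragment_length_mean,fragment_length_sd Physical fragment length
#'   (bp).
#' @param read_length Mate length (bp).
#' @param pairs_per_fragment_mean Mean read pairs per fragment
#'   (`1 + Poisson(mean - 1)`). The default 12 keeps most single-fragment
#'   barcodes above the 2 kb feature floor.
#' @param insert_size Outer distance between mate starts (bp).
#' @param substitution_error_rate Per-base substitution probability.
#' @param seed Integer seed; all generators are bit-reproducible under it.
#'
#' @return A `linked_read_config` list.
#' @export
linked_read_config <- function(mean_fragments_per_barcode = 1.54,
                               fragment_length_mean = 20000,
                               fragment_length_sd = 5000,
                               read_length = 100,
                               pairs_per_fragment_mean = 12,
                               insert_size = 350,
                               substitution_error_rate = 0.001,
                               seed = 1L) {
  stopifnot(
    mean_fragments_per_barcode >= 1,
    fragment_length_mean > 0, fragment_length_sd >= 0,
    read_length > 0, pairs_per_fragment_mean >= 1,
    insert_size >= 2 * read_length || insert_size >= read_length,
    substitution_error_rate >= 0, substitution_error_rate < 1
  )
  structure(
    list(
      mean_fragments_per_barcode = mean_fragments_per_barcode,
      fragment_length_mean = fragment_length_mean,
      fragment_length_sd = fragment_length_sd,
      read_length = as.integer(read_length),
      pairs_per_fragment_mean = pairs_per_fragment_mean,
      insert_size = as.integer(insert_size),
      substitution_error_rate = substitution_error_rate,
      seed = as.integer(seed)
    ),
    class = "linked_read_config"
  )
}

stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
  v / sum(v)
}

# Transition matrix: base composition set by GC, rows tilted by a per-genome
# log-normal bias (the tetranucleotide signature), and a scalar GC logit shift
# solved so the chain's stationary GC hits the target exactly.
markov_transitions <- function(gc, tilt) {
  base_p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  is_gc <- c(0, 1, 1, 0)
  build <- function(delta) {
    P <- sweep(exp(tilt + rep(delta * is_gc, each = 4)), 2, base_p, "*")
    P / rowSums(P)
  }
  gc_err <- function(delta) {
    pi <- stationary_distribution(build(delta))
    (pi[2] + pi[3]) - gc
  }
  delta <- stats::uniroot(gc_err, c(-6, 6), tol = 1e-10)$root
  build(delta)
}

# Per-genome transition-row tilts: seeded Gaussian directions orthogonalised
# across genomes (QR), all scaled to the same magnitude, so every pair of
# genomes carries a distinct compositional signature by construction rather
# than by luck of the draw. Beyond 16 genomes (the tilt dimension) additional
# genomes fall back to independent Gaussian directions.
genome_tilts <- function(n_genomes, sd) {
  if (sd <= 0) {
    return(replicate(n_genomes, matrix(0, 4, 4), simplify = FALSE))
  }
  # a constant added to a transition row is absorbed by row normalisation, so
  # only the row-centred part of a tilt is effective (12 of 16 dims); draw
  # directions there so none of a genome's signature is silently lost
  n_ortho <- min(n_genomes, 12L)
  raw <- matrix(rnorm(16 * n_ortho), 16, n_ortho)
  centred <- apply(raw, 2, function(v) {
    m <- matrix(v, 4, 4)
    as.vector(m - rowMeans(m))
  })
  q <- qr.Q(qr(centred))
  dirs <- lapply(seq_len(n_ortho), function(g) matrix(q[, g], 4, 4))
  if (n_genomes > n_ortho) {
    extra <- lapply(seq_len(n_genomes - n_ortho), function(g) {
      m <- matrix(rnorm(16), 4, 4)
      m <- m - rowMeans(m)
      m / sqrt(sum(m^2))
    })
    dirs <- c(dirs, extra)
  }
  # norm 4*sd matches the expected Frobenius norm of a 4x4 N(0, sd^2) draw
  lapply(dirs, function(m) m * (4 * sd))
}

sample_markov_sequence <- function(n, P) {
  cum <- t(apply(P, 1, cumsum))
  pi0 <- stationary_distribution(P)
  s <- integer(n)
  s[1] <- sample.int(4, 1, prob = pi0)
  u <- runif(n)
  for (i in 2:n) {
    s[i] <- 1L + sum(u[i] > cum[s[i - 1L], ])
  }
  paste(BASES[s], collapse = "")
}

#' Simulate community genomes
#'
#' Genomes are first-order Markov chains whose transition rows carry a
#' per-genome random log-tilt (distinct tetranucleotide signatures) and whose
#' stationary GC is calibrated to the configured target, so realized GC
#' concentrates within a fraction of a point for 100 kb genomes.
#'
#' @param config A [community_config()].
#' @param seed Integer seed.
#'
#' @return Tibble with `genome`, `seq`, `length`, `abundance`, `gc_target`,
#'   `gc_realized`.
#' @export
simulate_genomes <- function(config, seed = 1L) {
  stopifnot(inherits(config, "community_config"))
  with_seed(seed, {
    tilts <- genome_tilts(config$n_genomes, config$tnf_bias_sd)
    rows <- purrr::map(seq_len(config$n_genomes), function(g) {
      tilt <- tilts[[g]]
      P <- markov_transitions(config$gc_contents[g], tilt)
      seq <- sample_markov_sequence(config$genome_length[g], P)
      gc <- sum(strsplit(seq, "")[[1]] %in% c("G", "C")) / nchar(seq)
      tibble(
        genome = paste0("genome", g),
        seq = seq,
        length = nchar(seq),
        abundance = config$abundances[g],
        gc_target = config$gc_contents[g],
        gc_realized = gc
      )
    })
    dplyr::bind_rows(rows)
  })
}

revcomp <- function(x) {
  unname(as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x))
  ))
}

inject_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  len <- nchar(seqs)
  n_err <- rbinom(1, sum(len), rate)
  if (n_err == 0) return(seqs)
  idx <- sample.int(length(seqs), n_err, replace = TRUE, prob = len)
  pos <- 1L + floor(runif(n_err) * len[idx])
  for (j in seq_len(n_err)) {
    i <- idx[j]; p <- pos[j]
    old <- substr(seqs[i], p, p)
    alt <- setdiff(BASES, old)
    substr(seqs[i], p, p) <- alt[sample.int(length(alt), 1)]
  }
  seqs
}

stlfr_barcode_names <- function(n) {
  i <- seq_len(n) - 1L
  sprintf("%d_%d_%d", i %/% (1536L * 1536L) + 1L,
          (i %/% 1536L) %% 1536L + 1L, i %% 1536L + 1L)
}

#' Simulate barcoded linked-reads with ground truth
#'
#' Each barcode draws `1 + Poisson(mean - 1)` physical fragments; fragments
#' pick a source genome proportional to abundance times length, land uniformly
#' on it, and shed paired-end reads at uniform positions. Substitution errors
#' are applied per base. All coordinates in the truth tables are 0-based
#' half-open on the source genome.
#'
#' @param genomes Tibble from [simulate_genomes()].
#' @param lrc A [linked_read_config()].
#' @param n_barcodes Number of barcodes to emit.
#' @param sequences Emit read sequences (default `TRUE`). `FALSE` skips
#'   sequence extraction and error injection and returns `reads = NULL`;
#'   the truth tables are unaffected — useful for large fragment-statistics
#'   simulations where only coordinates matter.
#'
#' @return List with `reads` (read-pair tibble as in [read_linked_fastq()],
#'   stLFR technology), `truth_pairs` (one row per emitted read pair:
#'   `read_id`, `barcode`, `genome`, `fragment_id`, mate coordinates) and
#'   `truth_fragments` (one row per fragment: `fragment_id`, `barcode`,
#'   `genome`, `start`, `end`, `n_pairs`).
#' @export
simulate_linked_reads <- function(genomes, lrc, n_barcodes = 1000,
                                  sequences = TRUE) {
  stopifnot(inherits(lrc, "linked_read_config"), nrow(genomes) >= 1)
  with_seed(lrc$seed, {
    rl <- lrc$read_length
    ins <- max(lrc$insert_size, 2L * rl)
    barcodes <- stlfr_barcode_names(n_barcodes)

    n_frag <- 1L + rpois(n_barcodes, lrc$mean_fragments_per_barcode - 1)
    frag_bc <- rep.int(seq_len(n_barcodes), n_frag)
    n_f <- length(frag_bc)
    g_idx <- sample.int(nrow(genomes), n_f, replace = TRUE,
                        prob = genomes$abundance * genomes$length)
    g_len <- genomes$length[g_idx]
    f_len <- pmax(round(rnorm(n_f, lrc$fragment_length_mean,
                              lrc$fragment_length_sd)), ins)
    f_len <- pmin(f_len, g_len)
    f_start <- floor(runif(n_f) * (g_len - f_len + 1))

    n_pairs_f <- 1L + rpois(n_f, lrc$pairs_per_fragment_mean - 1)
    p_frag <- rep.int(seq_len(n_f), n_pairs_f)
    n_p <- length(p_frag)
    p_off <- floor(runif(n_p) * (f_len[p_frag] - ins + 1))
    s1 <- f_start[p_frag] + p_off            # 0-based start of mate 1
    s2 <- s1 + ins - rl                      # 0-based start of mate 2
    read_id <- sprintf("sim%08d", seq_len(n_p))
    reads <- NULL
    if (sequences) {
      gseq <- genomes$seq[g_idx[p_frag]]
      m1 <- substring(gseq, s1 + 1, s1 + rl)
      m2 <- revcomp(substring(gseq, s2 + 1, s2 + rl))
      m1 <- inject_substitutions(m1, lrc$substitution_error_rate)
      m2 <- inject_substitutions(m2, lrc$substitution_error_rate)
      qual <- strrep("I", rl)
      reads <- tibble(
        read_id = read_id,
        seq1 = m1, qual1 = qual,
        seq2 = m2, qual2 = qual,
        barcode = barcodes[frag_bc[p_frag]],
        technology = "stlfr"
      )
    }
    truth_pairs <- tibble(
      read_id = read_id,
      barcode = barcodes[frag_bc[p_frag]],
      genome = genomes$genome[g_idx[p_frag]],
      fragment_id = p_frag,
      start1 = s1, end1 = s1 + rl,
      start2 = s2, end2 = s2 + rl
    )
    truth_fragments <- tibble(
      fragment_id = seq_len(n_f),
      barcode = barcodes[frag_bc],
      genome = genomes$genome[g_idx],
      start = f_start, end = f_start + f_len,
      n_pairs = n_pairs_f
    )
    list(reads = reads, truth_pairs = truth_pairs,
         truth_fragments = truth_fragments)
  })
}

#' Ground-truth alignments from a simulated truth table
#'
#' Collapses the per-pair truth coordinates to the pair-level alignment
#' records that [reconstruct_fragments()] consumes (leftmost mate start,
#' rightmost mate end), sorted by reference and coordinate.
#'
#' @param truth_pairs `truth_pairs` tibble from [simulate_linked_reads()].
#' @return Alignment tibble with `barcode`, `ref`, `start`, `end`, `read_id`.
#' @export
truth_alignments <- function(truth_pairs) {
  truth_pairs |>
    dplyr::transmute(
      barcode = .data$barcode, ref = .data$genome,
      start = pmin(.data$start1, .data$start2),
      end = pmax(.data$end1, .data$end2),
      read_id = .data$read_id
    ) |>
    dplyr::arrange(.data$ref, .data$start)
}

#' Simulate long reads
#'
#' Substrate for virtual barcoding: long reads sampled from the community in
#' proportion to abundance times length, with substitution errors.
#'
#' @param genomes Tibble from [simulate_genomes()].
#' @param n_reads Number of long reads.
#' @param length_mean,length_sd Read length distribution (bp).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#'
#' @return List with `reads` (`read_id`, `seq`) and `truth` (`read_id`,
#'   `genome`, `start`, `end`, 0-based half-open).
#' @export
simulate_long_reads <- function(genomes, n_reads, length_mean = 10000,
                                length_sd = 2000, error_rate = 0.01,
                                seed = 1L) {
  stopifnot(nrow(genomes) >= 1)
  with_seed(seed, {
    if (n_reads == 0) {
      return(list(
        reads = tibble(read_id = character(), seq = character()),
        truth = tibble(read_id = character(), genome = character(),
                       start = integer(), end = integer())
      ))
    }
    g_idx <- sample.int(nrow(genomes), n_reads, replace = TRUE,
                        prob = genomes$abundance * genomes$length)
    g_len <- genomes$length[g_idx]
    len <- pmin(pmax(round(rnorm(n_reads, length_mean, length_sd)), 500), g_len)
    start <- floor(runif(n_reads) * (g_len - len + 1))
    seqs <- substring(genomes$seq[g_idx], start + 1, start + len)
    seqs <- inject_substitutions(seqs, error_rate)
    read_id <- sprintf("long%06d", seq_len(n_reads))
    list(
      reads = tibble(read_id = read_id, seq = seqs),
      truth = tibble(read_id = read_id, genome = genomes$genome[g_idx],
                     start = start, end = start + len)
    )
  })
}

#' Write sequences to FASTA
#'
#' @param x Tibble with an id column and a `seq` column (first column is used
#'   as the record name unless a `genome`/`read_id` column exists).
#' @param path Output path (`.gz` for compression).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  id_col <- intersect(c("genome", "read_id", "contig"), names(x))[1]
  if (is.na(id_col)) id_col <- names(x)[1]
  s <- Biostrings::DNAStringSet(x$seq)
  names(s) <- x[[id_col]]
  Biostrings::writeXStringSet(s, path, compress = grepl("\\.gz$", path))
  invisible(path)
}
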