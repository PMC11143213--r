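# Independent brute-force oracles. These re-derive expected results by direct
# enumeration, sharing no code with the implementation they check.

oracle_canonical <- function(kmer) {
  rc <- revcomp_chr(kmer)
  if (rc < kmer) rc else kmer
}

# every k-length window of every sequence, N-containing windows skipped
oracle_windows <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (!grepl("[^ACGT]", w)) out <- c(out, w)
    }
  }
  out
}

oracle_kmer_table <- function(seqs, k) {
  w <- vapply(oracle_windows(seqs, k), oracle_canonical, character(1))
  table(w)
}

oracle_features <- function(group_seqs, all_seqs, k = 15, max_freq = 4000,
                            bin_width = 10, n_bins = 400) {
  global <- oracle_kmer_table(all_seqs, k)
  xa <- numeric(n_bins)
  for (w in oracle_windows(group_seqs, k)) {
    f <- as.numeric(global[oracle_canonical(w)])
    if (is.na(f) || f > max_freq) next
    xa[ceiling(f / bin_width)] <- xa[ceiling(f / bin_width)] + 1
  }
  tnf_keys <- sort(unique(vapply(
    apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)), 1, paste,
          collapse = ""),
    oracle_canonical, character(1)
  )))
  xt <- setNames(numeric(length(tnf_keys)), tnf_keys)
  for (w in oracle_windows(group_seqs, 4)) {
    key <- oracle_canonical(w)
    xt[key] <- xt[key] + 1
  }
  norm <- function(v) if (sum(v) > 0) v / sum(v) else v
  list(x_a = norm(xa), x_t = unname(norm(xt)))
}

# exhaustive minimum-WCSS bipartition of <= 12 points
oracle_best_2partition <- function(x) {
  n <- nrow(x)
  best <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    wcss <- 0
    for (g in list(which(grp), which(!grp))) {
      c_g <- colMeans(x[g, , drop = FALSE])
      wcss <- wcss + sum(sweep(x[g, , drop = FALSE], 2, c_g)^2)
    }
    if (is.null(best) || wcss < best$wcss) best <- list(grp = grp, wcss = wcss)
  }
  best
}

# direct application of the chaining rules, one barcode/ref at a time
oracle_fragments <- function(alignments, gap = 10000, min_pairs = 2,
                             min_len = 1000) {
  out <- list()
  for (bc in unique(alignments$barcode)) {
    for (rf in unique(alignments$ref[alignments$barcode == bc])) {
      a <- alignments[alignments$barcode == bc & alignments$ref == rf, ]
      a <- a[order(a$start), ]
      chain <- list(a[1, ])
      for (i in seq_len(nrow(a))[-1]) {
        last <- chain[[length(chain)]]
        if (a$start[i] - max(last$start) <= gap) {
          chain[[length(chain)]] <- rbind(last, a[i, ])
        } else {
          chain[[length(chain) + 1]] <- a[i, ]
        }
      }
      for (ch in chain) {
        len <- max(ch$end) - min(ch$start)
        if (length(unique(ch$read_id)) >= min_pairs && len >= min_len) {
          out[[length(out) + 1]] <- tibble::tibble(
            barcode = bc, ref = rf, start = min(ch$start), end = max(ch$end),
            read_pair_count = length(unique(ch$read_id)), length = len
          )
        }
      }
    }
  }
  if (length(out) == 0) return(NULL)
  dplyr::bind_rows(out)
}

# per-pair scan of the retention rule
oracle_retained <- function(pair_ids, alignments, depths, t) {
  high <- depths$contig[depths$mean_depth > t]
  vapply(pair_ids, function(id) {
    hits <- alignments$contig[alignments$read_id == id]
    !any(hits %in% high)
  }, logical(1))
}
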