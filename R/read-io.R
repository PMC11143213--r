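#' Barcode dialects
#'
#' Linked-read technologies encode the bead barcode differently in FASTQ
#' headers. `linkbin` never auto-detects the dialect; it is always an explicit
#' argument because header conventions are ambiguous across vendors.
#'
#' * `stlfr` — barcode appended to the read id after the last `#`
#'   (e.g. `read1/1#123_456_789`); the all-zero token `0_0_0` marks an
#'   unresolved bead and is treated as absent.
#' * `tenx`, `tellseq`, `virtual` — barcode carried in a `BX:Z:` tag in the
#'   header comment (e.g. `read9 BX:Z:ACGTACGT-1`).
#'
#' @name barcode_dialects
#' @keywords internal
NULL

barcode_dialects <- c("stlfr", "tenx", "tellseq", "virtual")

check_dialect <- function(dialect) {
  if (length(dialect) != 1 || !dialect %in% barcode_dialects) {
    abort(paste0("`dialect` must be one of: ",
                 paste(barcode_dialects, collapse = ", ")))
  }
  dialect
}

#' Parse a barcode from a FASTQ header
#'
#' @param header Character vector of FASTQ title lines (without the leading
#'   `@`).
#' @param dialect One of `"stlfr"`, `"tenx"`, `"tellseq"`, `"virtual"`; see
#'   [barcode_dialects].
#' @param line Optional integer vector of source line numbers used in error
#'   messages for malformed headers.
#'
#' @return Character vector of barcodes, `NA` where the barcode is absent
#'   (missing token, or the dialect's null token such as stLFR `0_0_0`).
#' @export
#'
#' @examples
#' parse_barcode("r1/1#123_456_789", "stlfr")
#' parse_barcode("r1/1#0_0_0", "stlfr")       # null token -> NA
#' parse_barcode("r9 BX:Z:ACGTACGT-1", "tenx")
parse_barcode <- function(header, dialect, line = NULL) {
  check_dialect(dialect)
  if (dialect == "stlfr") {
    id_token <- sub("\\s.*$", "", header)
    bad <- !grepl("#", id_token, fixed = TRUE)
    if (any(bad)) {
      where <- if (!is.null(line)) line[bad][1] else which(bad)[1]
      abort(paste0("malformed stLFR header (no '#' barcode separator) at line ",
                   where, ": ", header[bad][1]))
    }
    bc <- sub("^.*#", "", id_token)
    bc[bc == "" | grepl("^0(_0)*$", bc)] <- NA_character_
    bc
  } else {
    m <- regmatches(header, regexpr("BX:Z:[^\\s\t]+", header, perl = TRUE))
    bc <- rep(NA_character_, length(header))
    has <- grepl("BX:Z:", header, fixed = TRUE)
    bc[has] <- sub("^BX:Z:", "", m)
    bc[!is.na(bc) & bc == ""] <- NA_character_
    bc
  }
}

strip_mate_suffix <- function(id) sub("/[12]$", "", id)

fastq_to_tibble <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    header = names(x),
    seq = unname(as.character(x)),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Read barcoded paired-end FASTQ
#'
#' Reads linked-read FASTQ in any supported barcode dialect, either
#' interleaved (one path) or as a two-file pair. Gzip input is handled
#' transparently.
#'
#' @param path Character vector: one interleaved FASTQ path, or
#'   `c(mate1, mate2)`.
#' @param dialect Barcode dialect; see [barcode_dialects].
#'
#' @return A tibble with one row per read pair: `read_id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`, `barcode` (`NA` when absent), `technology`.
#' @export
read_linked_fastq <- function(path, dialect) {
  check_dialect(dialect)
  if (length(path) == 1) {
    all <- fastq_to_tibble(path)
    if (nrow(all) %% 2 != 0) {
      abort("interleaved FASTQ has an odd number of records")
    }
    r1 <- all[seq(1, nrow(all), by = 2), ]
    r2 <- all[seq(2, nrow(all), by = 2), ]
  } else if (length(path) == 2) {
    r1 <- fastq_to_tibble(path[1])
    r2 <- fastq_to_tibble(path[2])
    if (nrow(r1) != nrow(r2)) abort("mate files differ in record count")
  } else {
    abort("`path` must be one interleaved file or c(mate1, mate2)")
  }
  barcode <- parse_barcode(r1$header, dialect)
  read_id <- strip_mate_suffix(sub("\\s.*$", "", r1$header))
  if (dialect == "stlfr") {
    read_id <- strip_mate_suffix(sub("#.*$", "", sub("\\s.*$", "", r1$header)))
  }
  tibble(
    read_id = read_id,
    seq1 = r1$seq, qual1 = r1$qual,
    seq2 = r2$seq, qual2 = r2$qual,
    barcode = barcode,
    technology = dialect
  )
}

format_linked_header <- function(read_id, barcode, dialect, mate) {
  if (dialect == "stlfr") {
    bc <- ifelse(is.na(barcode), "0_0_0", barcode)
    paste0(read_id, "/", mate, "#", bc)
  } else {
    ifelse(is.na(barcode), read_id, paste0(read_id, " BX:Z:", barcode))
  }
}

write_fastq_records <- function(headers, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- headers
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(quals),
    compress = grepl("\\.gz$", path)
  )
}

#' Write barcoded paired-end FASTQ
#'
#' Inverse of [read_linked_fastq()]: sequences, qualities and barcodes
#' round-trip byte-identically per dialect.
#'
#' @param reads Tibble as returned by [read_linked_fastq()].
#' @param path One interleaved output path or `c(mate1, mate2)`; `.gz` suffix
#'   enables compression.
#' @param dialect Barcode dialect; see [barcode_dialects].
#'
#' @return `path`, invisibly.
#' @export
write_linked_fastq <- function(reads, path, dialect) {
  check_dialect(dialect)
  h1 <- format_linked_header(reads$read_id, reads$barcode, dialect, 1)
  h2 <- format_linked_header(reads$read_id, reads$barcode, dialect, 2)
  if (length(path) == 1) {
    n <- nrow(reads)
    idx <- rep(seq_len(n), each = 2)
    mate <- rep(c(1L, 2L), n)
    headers <- ifelse(mate == 1, h1[idx], h2[idx])
    seqs <- ifelse(mate == 1, reads$seq1[idx], reads$seq2[idx])
    quals <- ifelse(mate == 1, reads$qual1[idx], reads$qual2[idx])
    write_fastq_records(headers, seqs, quals, path)
  } else if (length(path) == 2) {
    write_fastq_records(h1, reads$seq1, reads$qual1, path[1])
    write_fastq_records(h2, reads$seq2, reads$qual2, path[2])
  } else {
    abort("`path` must be one interleaved file or c(mate1, mate2)")
  }
  invisible(path)
}

#' Group read pairs by barcode
#'
#' Collects all read pairs sharing a barcode into one group (the unit of
#' binning) when their total sequence length reaches `min_total_bases`
#' (default 2 kb, below which k-mer features are too noisy to be stable).
#' Pairs with no barcode or in undersized groups go to a leftover pool that
#' downstream stages route into the shared/original-assembly branch. Groups
#' preserve input read order; group order follows first appearance.
#'
#' @param reads Tibble of read pairs (see [read_linked_fastq()]).
#' @param min_total_bases Minimum summed mate length per barcode (default
#'   2000).
#'
#' @return A list with `groups` — a tibble with `barcode`, `n_pairs`,
#'   `total_bases` and a `pairs` list-column of read-pair tibbles — and
#'   `leftover`, the pooled read pairs. Together they partition the input
#'   exactly.
#' @export
group_by_barcode <- function(reads, min_total_bases = 2000) {
  empty_groups <- tibble(
    barcode = character(), n_pairs = integer(),
    total_bases = integer(), pairs = list()
  )
  if (nrow(reads) == 0) {
    return(list(groups = empty_groups, leftover = reads))
  }
  reads <- dplyr::mutate(
    reads,
    .bases = nchar(.data$seq1) + nchar(.data$seq2)
  )
  with_bc <- dplyr::filter(reads, !is.na(.data$barcode))
  totals <- with_bc |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      total_bases = sum(.data$.bases),
      .by = "barcode"
    )
  keep <- totals$barcode[totals$total_bases >= min_total_bases]
  grouped <- with_bc |>
    dplyr::filter(.data$barcode %in% keep) |>
    dplyr::select(-".bases") |>
    tidyr::nest(pairs = -"barcode") |>
    dplyr::left_join(totals, by = "barcode") |>
    dplyr::select("barcode", "n_pairs", "total_bases", "pairs")
  leftover <- reads |>
    dplyr::filter(is.na(.data$barcode) | !.data$barcode %in% keep) |>
    dplyr::select(-".bases")
  list(groups = if (nrow(grouped)) grouped else empty_groups,
       leftover = leftover)
}
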