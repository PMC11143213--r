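#' Read barcoded alignments from SAM/BAM
#'
#' Loads primary alignments with their barcode (`BX`-style tag, as written by
#' aligners run with the option that carries the FASTQ comment through, e.g.
#' bwa mem `-C`), the reference, the 0-based start/end and the number of
#' reference bases covered (from the CIGAR). Secondary and supplementary
#' records are dropped.
#'
#' @param path SAM or BAM file.
#' @param tag Barcode tag name (default `"BX"`).
#'
#' @return Tibble `read_id`, `barcode`, `ref`, `start`, `end` (0-based
#'   half-open), `aligned_bases`, `primary`.
#' @export
read_barcoded_alignments <- function(path, tag = "BX") {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE)) {
    abort("Rsamtools and GenomicAlignments are required to read SAM/BAM")
  }
  bam <- if (grepl("\\.sam$", path)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else {
    path
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar"),
    tag = tag,
    flag = Rsamtools::scanBamFlag(
      isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
      isUnmappedQuery = FALSE
    )
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar)
  aligned <- GenomicAlignments::cigarWidthAlongQuerySpace(
    rec$cigar, after.soft.clipping = TRUE
  )
  tibble(
    read_id = rec$qname,
    barcode = as.character(rec$tag[[tag]] %||% NA_character_),
    ref = as.character(rec$rname),
    start = rec$pos - 1L,
    end = rec$pos - 1L + width,
    aligned_bases = aligned,
    primary = TRUE
  )
}
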