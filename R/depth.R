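#' Mean read depth per contig
#'
#' Depth is total aligned bases divided by contig length — a plain untrimmed
#' mean over every position (contigs without alignments get 0). Only primary
#' alignments should be supplied; rows flagged `primary = FALSE` are dropped.
#'
#' @param alignments Tibble with `contig` and `aligned_bases` (optionally
#'   `primary`).
#' @param contig_lengths Tibble with `contig`, `length`.
#'
#' @return Tibble `contig`, `length`, `mean_depth`, one row per contig in
#'   `contig_lengths` (order preserved).
#' @export
contig_depths <- function(alignments, contig_lengths) {
  if ("primary" %in% names(alignments)) {
    alignments <- dplyr::filter(alignments, .data$primary)
  }
  unknown <- setdiff(unique(alignments$contig), contig_lengths$contig)
  if (length(unknown) > 0) {
    abort(paste0("alignments reference unknown contig(s): ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  totals <- alignments |>
    dplyr::summarise(bases = sum(.data$aligned_bases), .by = "contig")
  contig_lengths |>
    dplyr::left_join(totals, by = "contig") |>
    dplyr::mutate(
      mean_depth = dplyr::coalesce(.data$bases, 0) / .data$length
    ) |>
    dplyr::select("contig", "length", "mean_depth")
}

#' Collect reads not mapped to high-depth contigs
#'
#' The low-abundance partition at threshold `t`: a read pair is retained iff
#' neither mate has a primary alignment to any contig whose mean depth exceeds
#' `t`. Rerunning at increasing thresholds ("multi-thresholding", default
#' `T = c(10, 30)`) peels back high-abundance genomes so progressively rarer
#' ones dominate the reassembly input; retained sets are nested upward in `t`.
#'
#' @param pair_ids Character vector of all read-pair ids (the universe).
#' @param alignments Tibble with `read_id`, `contig` (optionally `primary`);
#'   one row per mate alignment.
#' @param depths Tibble from [contig_depths()] computed from the same
#'   alignments.
#' @param t Depth threshold.
#'
#' @return A `partition_result` tibble: `read_id`, `retained` (logical), with
#'   `threshold` as an attribute.
#' @export
collect_low_abundance_reads <- function(pair_ids, alignments, depths, t) {
  if ("primary" %in% names(alignments)) {
    alignments <- dplyr::filter(alignments, .data$primary)
  }
  high <- depths$contig[depths$mean_depth > t]
  excluded <- unique(alignments$read_id[alignments$contig %in% high])
  out <- tibble(read_id = pair_ids, retained = !pair_ids %in% excluded)
  attr(out, "threshold") <- t
  class(out) <- c("partition_result", class(out))
  out
}

#' Partition reads at several depth thresholds
#'
#' @param pair_ids,alignments,depths See [collect_low_abundance_reads()].
#' @param thresholds Strictly increasing depth thresholds (default
#'   `c(10, 30)`).
#' @return Tibble with `threshold`, `n_retained`, and a `retained` list-column
#'   of read-pair ids.
#' @export
partition_by_depth <- function(pair_ids, alignments, depths,
                               thresholds = c(10, 30)) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("`thresholds` must be strictly increasing")
  }
  purrr::map(thresholds, function(t) {
    res <- collect_low_abundance_reads(pair_ids, alignments, depths, t)
    tibble(threshold = t, n_retained = sum(res$retained),
           retained = list(res$read_id[res$retained]))
  }) |>
    dplyr::bind_rows()
}
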