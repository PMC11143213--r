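#' Classify MAG quality tiers
#'
#' Tiers follow the minimum-information-about-MAGs convention, assigned by
#' first matching rule:
#' * `near_complete` — completeness > 90, contamination < 5, 5S + 16S + 23S
#'   rRNAs all detected, and >= 18 tRNAs;
#' * `high` — completeness > 90 and contamination < 5;
#' * `medium` — completeness >= 50 and contamination < 10;
#' * `low` — everything else.
#'
#' @param metrics Tibble with `completeness`, `contamination` (percent),
#'   `has_5s`, `has_16s`, `has_23s` (logical), `trna_count`; extra columns
#'   (e.g. `n50`, `mean_depth`, a MAG id) pass through.
#'
#' @return `metrics` with a `tier` factor column
#'   (`near_complete > high > medium > low`).
#' @export
classify_mag <- function(metrics) {
  stopifnot(all(metrics$completeness >= 0 & metrics$completeness <= 100),
            all(metrics$contamination >= 0 & metrics$contamination <= 100),
            all(metrics$trna_count >= 0))
  metrics |>
    dplyr::mutate(
      tier = factor(
        dplyr::case_when(
          .data$completeness > 90 & .data$contamination < 5 &
            .data$has_5s & .data$has_16s & .data$has_23s &
            .data$trna_count >= 18 ~ "near_complete",
          .data$completeness > 90 & .data$contamination < 5 ~ "high",
          .data$completeness >= 50 & .data$contamination < 10 ~ "medium",
          TRUE ~ "low"
        ),
        levels = c("near_complete", "high", "medium", "low")
      )
    )
}

#' Alignment-level sequence identity
#'
#' `(total_aligned - mismatches) / total_aligned`.
#'
#' @param total_aligned Total aligned length in bp (> 0).
#' @param mismatches Mismatching bases (0 <= mismatches <= total_aligned).
#' @return Identity fraction in `[0, 1]`.
#' @export
sequence_identity <- function(total_aligned, mismatches) {
  if (any(total_aligned <= 0)) abort("`total_aligned` must be positive")
  if (any(mismatches < 0 | mismatches > total_aligned)) {
    abort("`mismatches` must lie in [0, total_aligned]")
  }
  (total_aligned - mismatches) / total_aligned
}

#' Count near-complete MAGs under optional thresholds
#'
#' @param metrics Tibble accepted by [classify_mag()] (a `tier` column is
#'   computed if absent).
#' @param min_n50 Optional: count only NCMAGs with `n50 > min_n50` (strict,
#'   e.g. `1e6` for "N50 > 1 Mb").
#' @param max_depth Optional: count only NCMAGs with `mean_depth <= max_depth`.
#'
#' @return Integer count.
#' @export
count_ncmags <- function(metrics, min_n50 = NULL, max_depth = NULL) {
  if (nrow(metrics) == 0) return(0L)
  if (!"tier" %in% names(metrics)) metrics <- classify_mag(metrics)
  nc <- dplyr::filter(metrics, .data$tier == "near_complete")
  if (!is.null(min_n50)) {
    if (!"n50" %in% names(nc)) abort("`min_n50` given but no `n50` column")
    nc <- dplyr::filter(nc, .data$n50 > min_n50)
  }
  if (!is.null(max_depth)) {
    if (!"mean_depth" %in% names(nc)) {
      abort("`max_depth` given but no `mean_depth` column")
    }
    nc <- dplyr::filter(nc, .data$mean_depth <= max_depth)
  }
  nrow(nc)
}
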