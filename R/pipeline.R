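#' Pipeline configuration
#'
#' Bundles the per-stage configurations and the external-assembler adapters.
#' Assemblers and mergers are never bundled: an adapter is a command template
#' with `{input}`, `{out}` and `{threads}` placeholders, or one of the
#' built-in mocks (`"mock"` assembler emits each read as a contig; `"mock"`
#' merger concatenates and deduplicates identical records) used for hermetic
#' tests.
#'
#' @param dialect Barcode dialect of the input FASTQ.
#' @param min_total_bases Barcode-group size floor (default 2000).
#' @param features A [feature_config()].
#' @param embedder An [embedder_config()].
#' @param clustering A [clustering_config()].
#' @param k Number of bins, or `NULL` to derive it from `diversity`.
#' @param diversity Shannon diversity used by [choose_k()] when `k` is `NULL`.
#' @param thresholds Depth thresholds for multi-threshold partitioning.
#' @param assembler,merger Adapter command templates or `"mock"`.
#' @param threads Threads substituted into adapter templates.
#' @param workdir Output directory.
#' @param seed Global seed; stage seeds derive from it.
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dialect = "stlfr", min_total_bases = 2000,
                            features = feature_config(),
                            embedder = embedder_config(),
                            clustering = clustering_config(),
                            k = NULL, diversity = NULL,
                            thresholds = c(10, 30),
                            assembler = "mock", merger = "mock",
                            threads = 1L, workdir = tempfile("linkbin_"),
                            seed = 1L) {
  check_dialect(dialect)
  if (is.null(k) && is.null(diversity)) {
    abort("provide `k` or `diversity` (exactly one drives the bin count)")
  }
  embedder$seed <- as.integer(seed)
  clustering$seed <- as.integer(seed)
  structure(
    list(dialect = dialect, min_total_bases = min_total_bases,
         features = features, embedder = embedder, clustering = clustering,
         k = k, diversity = diversity, thresholds = thresholds,
         assembler = assembler, merger = merger, threads = threads,
         workdir = workdir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

manifest_row <- function(stage, artifact, path, n_records, seconds) {
  tibble(
    stage = stage, artifact = artifact, path = path,
    md5 = if (!is.na(path) && file.exists(path))
      unname(tools::md5sum(path)) else NA_character_,
    n_records = n_records, seconds = round(seconds, 3)
  )
}

timed <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  val <- force(expr)
  list(value = val, seconds = proc.time()[["elapsed"]] - t0)
}

#' Run the read-binning pipeline
#'
#' End-to-end: group reads by barcode, build the global k-mer table, extract
#' features, train the embedder with weighted sampling, embed, cluster the
#' latent means into k bins, and write one FASTQ per bin plus a `shared`
#' FASTQ holding the leftover pool (unbarcoded and undersized-barcode pairs,
#' consumed by the ensemble stage, never multiplied into bins). Read counts
#' are conserved: bins plus shared equal the input exactly. Deterministic
#' under `config$seed`.
#'
#' @param reads Read-pair tibble, or FASTQ path(s) read with
#'   `config$dialect`.
#' @param config A [pipeline_config()].
#'
#' @return List with `assignment` (bin per barcode), `bin_files`,
#'   `shared_file`, `embedding`, `embedder`, `k`, and `manifest`.
#' @export
run_binning_pipeline <- function(reads, config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$workdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()

  if (is.character(reads)) {
    st <- timed(read_linked_fastq(reads, config$dialect))
    reads <- st$value
    manifest <- c(manifest, list(manifest_row(
      "io", "input", reads_path <- NA_character_, nrow(reads), st$seconds)))
  }
  n_input <- nrow(reads)

  st <- timed(group_by_barcode(reads, config$min_total_bases))
  grouping <- st$value
  manifest <- c(manifest, list(manifest_row(
    "group", "barcode_groups", NA_character_, nrow(grouping$groups),
    st$seconds)))

  st <- timed(build_kmer_table(reads, config$features))
  table <- st$value
  manifest <- c(manifest, list(manifest_row(
    "features", "kmer_table", NA_character_, length(table$code), st$seconds)))

  st <- timed(barcode_features(grouping$groups, table, config$features))
  features <- st$value
  manifest <- c(manifest, list(manifest_row(
    "features", "feature_records", NA_character_, nrow(features), st$seconds)))

  st <- timed(train_embedder(features, config$embedder))
  embedder <- st$value
  manifest <- c(manifest, list(manifest_row(
    "embedding", "embedder", NA_character_, nrow(embedder$log), st$seconds)))

  st <- timed(embed_barcodes(embedder, features))
  embedding <- st$value
  manifest <- c(manifest, list(manifest_row(
    "embedding", "latent_mu", NA_character_, nrow(embedding), st$seconds)))

  k <- config$k %||% choose_k(config$diversity, config$clustering$a_coefficient)
  st <- timed(cluster_latent(embedding, k, config$clustering))
  assignment <- st$value
  manifest <- c(manifest, list(manifest_row(
    "clustering", "bin_assignment", NA_character_, nrow(assignment),
    st$seconds)))

  st <- timed({
    binned <- reads |>
      dplyr::inner_join(assignment, by = "barcode")
    bin_files <- character(k)
    for (b in 0:(k - 1)) {
      path <- file.path(config$workdir, sprintf("bin_%03d.fq", b))
      write_linked_fastq(dplyr::filter(binned, .data$bin == b), path,
                         config$dialect)
      bin_files[b + 1] <- path
    }
    shared <- dplyr::anti_join(reads, assignment, by = "barcode")
    shared_file <- file.path(config$workdir, "shared.fq")
    write_linked_fastq(shared, shared_file, config$dialect)
    list(bin_files = bin_files, shared_file = shared_file,
         n_binned = nrow(binned), n_shared = nrow(shared))
  })
  emit <- st$value
  if (emit$n_binned + emit$n_shared != n_input) {
    abort("read conservation violated at bin emission")
  }
  for (i in seq_along(emit$bin_files)) {
    manifest <- c(manifest, list(manifest_row(
      "emit", sprintf("bin_%03d", i - 1), emit$bin_files[i], NA_integer_,
      st$seconds / (k + 1))))
  }
  manifest <- c(manifest, list(manifest_row(
    "emit", "shared", emit$shared_file, emit$n_shared, st$seconds / (k + 1))))

  list(
    assignment = assignment, bin_files = emit$bin_files,
    shared_file = emit$shared_file, embedding = embedding,
    embedder = embedder, k = k, manifest = dplyr::bind_rows(manifest)
  )
}

#' Run the multi-threshold partition stage
#'
#' Computes contig depths from the alignments and writes, per threshold, the
#' FASTQ of read pairs that map to no contig deeper than the threshold.
#'
#' @param reads Read-pair tibble (the universe of pairs).
#' @param alignments Mate-level alignment tibble (`read_id`, `contig`,
#'   `aligned_bases`, optional `primary`).
#' @param contig_lengths Tibble `contig`, `length`.
#' @param config A [pipeline_config()] (supplies thresholds, dialect,
#'   workdir).
#'
#' @return List with `depths`, `partitions` (from [partition_by_depth()] plus
#'   a `path` column) and `manifest`.
#' @export
run_partition_pipeline <- function(reads, alignments, contig_lengths, config) {
  dir.create(config$workdir, recursive = TRUE, showWarnings = FALSE)
  depths <- contig_depths(alignments, contig_lengths)
  parts <- partition_by_depth(reads$read_id, alignments, depths,
                              config$thresholds)
  manifest <- list()
  paths <- character(nrow(parts))
  for (i in seq_len(nrow(parts))) {
    st <- timed({
      keep <- dplyr::filter(reads, .data$read_id %in% parts$retained[[i]])
      path <- file.path(config$workdir,
                        sprintf("low_t%g.fq", parts$threshold[i]))
      write_linked_fastq(keep, path, config$dialect)
      path
    })
    paths[i] <- st$value
    manifest <- c(manifest, list(manifest_row(
      "partition", sprintf("t=%g", parts$threshold[i]), st$value,
      parts$n_retained[i], st$seconds)))
  }
  parts$path <- paths
  list(depths = depths, partitions = parts,
       manifest = dplyr::bind_rows(manifest))
}

read_fasta_tibble <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(contig = names(x), seq = as.character(x))
}

substitute_template <- function(template, input, out, threads) {
  cmd <- gsub("{input}", paste(input, collapse = " "), template, fixed = TRUE)
  cmd <- gsub("{out}", out, cmd, fixed = TRUE)
  gsub("{threads}", as.character(threads), cmd, fixed = TRUE)
}

run_adapter <- function(template, input, out, threads) {
  cmd <- substitute_template(template, input, out, threads)
  res <- suppressWarnings(system2("sh", c("-c", shQuote(cmd)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  list(command = cmd, status = status, output = res)
}

#' Mock per-bin assembler
#'
#' Emits every read of a FASTQ as its own "contig"; stands in for an external
#' assembler in hermetic tests of pipeline plumbing.
#'
#' @param fastq Input FASTQ path.
#' @param out Output FASTA path.
#' @return `out`, invisibly.
#' @export
mock_assembler <- function(fastq, out) {
  x <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  Biostrings::writeXStringSet(x, out)
  invisible(out)
}

#' Merge contig sets (ensemble stage)
#'
#' Runs the configured merger over the contig sets from the binning, the
#' multi-threshold, the local and the original assembly branches, in that
#' order. With the built-in mock merger the result is the deterministic
#' concatenation of all records with exact duplicates (identical sequences)
#' removed once; command adapters are invoked with `{input}`, `{out}`,
#' `{threads}` substituted and their exact command line recorded.
#'
#' @param contig_sets Named character vector of FASTA paths (e.g. `bin`,
#'   `low`, `local`, `original`).
#' @param out Output FASTA path.
#' @param merger `"mock"` or a command template; `NULL` errors.
#' @param threads Threads for command adapters.
#'
#' @return List with `out`, `n_contigs` and `manifest`.
#' @export
run_ensemble <- function(contig_sets, out, merger = "mock", threads = 1L) {
  if (is.null(merger)) {
    abort("merger adapter not configured; set `merger` to \"mock\" or a command template")
  }
  missing <- contig_sets[!file.exists(contig_sets)]
  if (length(missing)) {
    abort(paste0("contig set file(s) missing: ",
                 paste(missing, collapse = ", ")))
  }
  st <- timed({
    if (identical(merger, "mock")) {
      all <- purrr::map(unname(contig_sets), read_fasta_tibble) |>
        dplyr::bind_rows() |>
        dplyr::distinct(.data$seq, .keep_all = TRUE)
      write_fasta(all, out)
      list(command = "mock merger (concatenate + deduplicate)",
           n = nrow(all))
    } else {
      res <- run_adapter(merger, contig_sets, out, threads)
      if (res$status != 0) {
        abort(paste0("merger adapter failed (status ", res$status, "): ",
                     paste(utils::tail(res$output, 5), collapse = "\n")))
      }
      list(command = res$command,
           n = length(Biostrings::fasta.seqlengths(out)))
    }
  })
  manifest <- manifest_row("ensemble", "merged_contigs", out,
                           st$value$n, st$seconds)
  manifest$command <- st$value$command
  list(out = out, n_contigs = st$value$n, manifest = manifest)
}
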