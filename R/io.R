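# Readers and writers for the package's file interfaces. Interval files use
# the BED convention on disk (0-based half-open); in memory, insertion points
# are 1-based positions.

#' Read and write caller call files
#'
#' Calls are stored as BED-derived TSV with one single-bp half-open interval
#' per call: columns `chrom`, `start` (0-based), `end` (= start + 1),
#' `family`, `support_reads`, `caller_id`, `sample_id`, `tissue`. In memory
#' the 1-based point `pos = start + 1` is used.
#'
#' @param calls Call tibble (as produced by [simulate_calls()] or read back).
#' @param path File path.
#' @return `read_caller_calls()` returns a call tibble with a `patient_id`
#'   column recovered from `sample_id`; `write_caller_calls()` returns
#'   `path` invisibly.
#' @export
write_caller_calls <- function(calls, path) {
  out <- tibble(
    chrom = calls$chrom,
    start = calls$pos - 1L,
    end = calls$pos,
    family = calls$family,
    support_reads = calls$support_reads,
    caller_id = calls$caller_id,
    sample_id = calls$sample_id,
    tissue = calls$tissue
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_caller_calls
#' @export
read_caller_calls <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "i", end = "i", family = "c",
    support_reads = "i", caller_id = "c", sample_id = "c", tissue = "c"))
  dplyr::transmute(df,
    .data$chrom, pos = .data$start + 1L, .data$family,
    .data$support_reads, .data$caller_id,
    patient_id = sub("\\.[^.]*$", "", .data$sample_id),
    .data$tissue, .data$sample_id)
}

#' Write each caller/sample call set to its own file
#'
#' One file per caller per sample, named `calls_<caller>_<sample>.tsv`.
#'
#' @param calls Combined call tibble.
#' @param dir Output directory (created if absent).
#' @return Invisible character vector of paths.
#' @export
write_call_files <- function(calls, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  groups <- dplyr::distinct(calls, .data$caller_id, .data$sample_id)
  paths <- purrr::pmap_chr(groups, function(caller_id, sample_id) {
    p <- file.path(dir, sprintf("calls_%s_%s.tsv", caller_id, sample_id))
    write_caller_calls(calls[calls$caller_id == caller_id &
      calls$sample_id == sample_id, ], p)
    p
  })
  invisible(paths)
}

#' Read and write a population panel file
#'
#' BED-derived TSV: `chrom`, `start`, `end`, `family`, `af`.
#'
#' @param panel Panel tibble with 1-based `pos`.
#' @param path File path.
#' @export
write_panel <- function(panel, path) {
  out <- tibble(chrom = panel$chrom, start = panel$pos - 1L,
    end = panel$pos, family = panel$family, af = panel$af)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "i", end = "i", family = "c", af = "d"))
  dplyr::transmute(df, .data$chrom, pos = .data$start + 1L,
    .data$family, .data$af)
}

#' Write genome features to standard formats
#'
#' Genes go to BED12 (one block per exon), enhancers to BED3 and the
#' tumor-suppressor list to a plain one-id-per-line text file.
#'
#' @param features A [feature_bundle()].
#' @param dir Output directory (created if absent).
#' @return Invisible named character vector of the three paths.
#' @export
write_features <- function(features, dir) {
  stopifnot(inherits(features, "te_feature_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(genes = file.path(dir, "genes.bed"),
    enhancers = file.path(dir, "enhancers.bed"),
    tumor_suppressors = file.path(dir, "tumor_suppressors.txt"))

  ex <- features$exons |>
    dplyr::arrange(.data$gene_id, .data$start) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      block_count = dplyr::n(),
      block_sizes = paste0(paste(.data$end - .data$start,
        collapse = ","), ","),
      block_starts_abs = list(.data$start),
      .groups = "drop")
  g <- dplyr::left_join(features$genes, ex, by = "gene_id")
  block_starts <- purrr::map2_chr(g$block_starts_abs, g$tx_start,
    function(s, t) paste0(paste(s - t, collapse = ","), ","))
  bed12 <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
    g$chrom, g$tx_start, g$tx_end, g$gene_id, g$strand,
    g$tx_start, g$tx_end, g$block_count, g$block_sizes, block_starts)
  writeLines(bed12, paths["genes"])

  writeLines(sprintf("%s\t%d\t%d", features$enhancers$chrom,
    as.integer(features$enhancers$start),
    as.integer(features$enhancers$end)), paths["enhancers"])
  writeLines(features$tumor_suppressors, paths["tumor_suppressors"])
  invisible(paths)
}

#' Read genome features from BED12 / BED / text files
#'
#' @param genes_path BED12 gene models (blocks = exons).
#' @param enhancers_path BED intervals.
#' @param tsg_path One gene id per line.
#' @return A [feature_bundle()].
#' @export
read_features <- function(genes_path, enhancers_path, tsg_path) {
  bed <- readr::read_tsv(genes_path, col_names = c("chrom", "tx_start",
    "tx_end", "gene_id", "score", "strand", "thick_start", "thick_end",
    "rgb", "block_count", "block_sizes", "block_starts"),
    col_types = "ciiccciicicc")
  genes <- bed[, c("gene_id", "chrom", "strand", "tx_start", "tx_end")]
  exons <- bed |>
    dplyr::mutate(
      size = lapply(strsplit(.data$block_sizes, ","), as.integer),
      off = lapply(strsplit(.data$block_starts, ","), as.integer)) |>
    dplyr::select("gene_id", "chrom", "tx_start", "size", "off") |>
    tidyr::unnest(c("size", "off")) |>
    dplyr::transmute(.data$gene_id, .data$chrom,
      start = .data$tx_start + .data$off,
      end = .data$tx_start + .data$off + .data$size)
  enh <- readr::read_tsv(enhancers_path,
    col_names = c("chrom", "start", "end"), col_types = "cii")
  tsg <- readLines(tsg_path)
  feature_bundle(genes = genes, exons = exons, enhancers = enh,
    tumor_suppressors = tsg[nzchar(tsg)])
}

#' Read and write expression count tables
#'
#' Long-format TSV: `feature_id`, `class`, `patient_id`, `tissue`,
#' `sample_id`, `count`.
#'
#' @param counts Expression tibble.
#' @param path File path.
#' @export
write_expression <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    feature_id = "c", class = "c", patient_id = "c", tissue = "c",
    sample_id = "c", count = "d"))
}

#' Read and write read-to-candidate-locus assignment tables
#'
#' On disk: TSV with `read_id` and a comma-separated `candidates` column;
#' in memory: long tibble `read_id`, `locus_id` as consumed by
#' [em_assign()].
#'
#' @param assignments Long tibble `read_id`, `locus_id`.
#' @param path File path.
#' @export
write_read_assignments <- function(assignments, path) {
  out <- assignments |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(candidates = paste(.data$locus_id, collapse = ","),
      .groups = "drop")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_read_assignments
#' @export
read_read_assignments <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(read_id = "c", candidates = "c"))
  df |>
    dplyr::mutate(locus_id = strsplit(.data$candidates, ",")) |>
    dplyr::select("read_id", "locus_id") |>
    tidyr::unnest("locus_id")
}

#' Write a complete synthetic cohort to a directory
#'
#' Emits per-caller per-sample call files, the panel, truth tables, genome
#' features, the expression table, the EM read-assignment table and the
#' generating configuration.
#'
#' @param cohort A `te_cohort` from [simulate_cohort()].
#' @param dir Output directory.
#' @return Invisible `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "te_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_call_files(cohort$calls, file.path(dir, "calls"))
  write_panel(cohort$panel, file.path(dir, "panel.tsv"))
  write_truth_tables(cohort$truth, file.path(dir, "truth"))
  write_features(cohort$features, file.path(dir, "features"))
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_read_assignments(cohort$read_assignments,
    file.path(dir, "read_assignments.tsv"))
  write_cohort_config(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
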