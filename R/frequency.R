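# Population allele-frequency annotation and normal-vs-tumor comparison.

#' Annotate insertions with population allele frequencies
#'
#' Matches each insertion to the nearest reference-panel entry of the same
#' family within `window_bp` and assigns a frequency bin: `private` (no panel
#' match), `low` (0 < af < 0.05) or `high` (af >= 0.05). The 0.05 boundary is
#' assigned to the high bin (closed upper bin); set `high_closed = FALSE` to
#' put exactly 0.05 in the low bin instead. Annotation is independent of
#' input order and idempotent.
#'
#' @param insertions Tibble with `chrom`, `pos`, `family` columns (e.g.
#'   consensus insertions).
#' @param panel Reference panel tibble: `chrom`, `pos`, `family`, `af` with
#'   0 < af <= 1 (emulating a population catalogue of polymorphic TE loci).
#' @param window_bp Matching window in bp (default 100).
#' @param af_threshold Boundary between low- and high-frequency bins.
#' @param high_closed Should `af == af_threshold` fall in the high bin?
#' @return `insertions` plus `panel_pos`, `panel_af` (`NA` when private) and
#'   `bin` (factor with levels private/low/high).
#' @export
annotate_frequencies <- function(insertions, panel, window_bp = 100,
                                 af_threshold = 0.05, high_closed = TRUE) {
  if (any(is.na(panel$af)) || any(panel$af <= 0 | panel$af > 1)) {
    abort("panel allele frequencies must lie in (0, 1].",
      class = "te_panel_error")
  }
  ins <- dplyr::mutate(insertions, .row = dplyr::row_number())
  best <- dplyr::inner_join(
    ins[, c(".row", "chrom", "pos", "family")],
    dplyr::rename(panel[, c("chrom", "pos", "family", "af")],
      panel_pos = "pos"),
    by = c("chrom", "family"), relationship = "many-to-many"
  ) |>
    dplyr::filter(abs(.data$pos - .data$panel_pos) <= window_bp) |>
    dplyr::arrange(abs(.data$pos - .data$panel_pos), .data$panel_pos) |>
    dplyr::distinct(.data$.row, .keep_all = TRUE)

  out <- dplyr::left_join(ins,
    best[, c(".row", "panel_pos", "af")], by = ".row") |>
    dplyr::select(-".row") |>
    dplyr::rename(panel_af = "af")
  out$bin <- factor(
    dplyr::case_when(
      is.na(out$panel_af) ~ "private",
      out$panel_af > af_threshold ~ "high",
      out$panel_af == af_threshold & high_closed ~ "high",
      .default = "low"
    ),
    levels = c("private", "low", "high")
  )
  out
}

#' Compare allele-frequency bin distributions between tissues
#'
#' Tests whether normal- and tumor-tissue insertions differ in their
#' population-frequency profile. The primary statistic is a two-sample
#' Kolmogorov-Smirnov test on the underlying matched allele frequencies with
#' private insertions mapped to frequency 0; because a three-bin
#' discretisation is statistically degenerate for KS, a chi-square test on
#' the 3 x 2 bin-count table is reported alongside as a companion statistic.
#'
#' @param normal_annotations,tumor_annotations Non-empty outputs of
#'   [annotate_frequencies()] for the two tissues.
#' @return A `te_freq_test` object: `statistic` and `p_value` (KS on AF
#'   values), `bin_counts` (tibble bin x tissue), `chisq_statistic`,
#'   `chisq_p_value`, and the two AF vectors. `tidy()` returns the bin
#'   counts; `glance()` the test results.
#' @export
compare_bin_distributions <- function(normal_annotations,
                                      tumor_annotations) {
  if (nrow(normal_annotations) == 0L || nrow(tumor_annotations) == 0L) {
    abort("both annotation sets must be non-empty.",
      class = "te_undefined_test_error")
  }
  af_of <- function(x) ifelse(is.na(x$panel_af), 0, x$panel_af)
  x <- af_of(normal_annotations)
  y <- af_of(tumor_annotations)
  ks <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))

  lev <- c("private", "low", "high")
  bins <- dplyr::bind_rows(
    tibble(tissue = "normal", bin = factor(normal_annotations$bin, lev)),
    tibble(tissue = "tumor", bin = factor(tumor_annotations$bin, lev))
  ) |>
    dplyr::count(.data$bin, .data$tissue, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "n",
      values_fill = 0L)
  mat <- as.matrix(bins[, c("normal", "tumor")])
  nonzero <- rowSums(mat) > 0
  chisq <- if (sum(nonzero) >= 2) {
    suppressWarnings(stats::chisq.test(mat[nonzero, , drop = FALSE]))
  } else {
    list(statistic = c("X-squared" = NA_real_), p.value = NA_real_)
  }

  structure(
    list(statistic = unname(ks$statistic), p_value = ks$p.value,
      method = "two-sample KS on matched allele frequencies (private = 0)",
      bin_counts = bins,
      chisq_statistic = unname(chisq$statistic),
      chisq_p_value = chisq$p.value,
      normal_af = x, tumor_af = y),
    class = "te_freq_test"
  )
}
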