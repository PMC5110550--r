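# EM assignment of multi-mapped reads and expression-distribution tests.

#' Expectation-maximization assignment of multi-mapped reads
#'
#' Fractionally allocates reads among their candidate TE loci. Starting from
#' a uniform abundance vector, the E-step assigns each read to its candidate
#' loci proportionally to the current abundances and the M-step sets each
#' locus abundance to the sum of incoming read fractions; iteration stops
#' when the largest abundance change drops below `tol` or after `max_iter`
#' iterations. Total abundance equals the read count after every iteration,
#' and the observed-data log-likelihood is non-decreasing (standard EM
#' guarantees for this multinomial mixture).
#'
#' This is a deliberately simple instance-level quantifier: no transcript
#' length normalisation and no mapping qualities, just the core principle of
#' abundance-proportional rescue of ambiguous repeat-derived reads.
#'
#' @param reads Tibble in long form: one row per (read, candidate locus)
#'   pair, columns `read_id` and `locus_id`. Every read needs at least one
#'   candidate by construction; candidate loci absent from `loci` are an
#'   error.
#' @param loci Optional character vector (or tibble with `locus_id`) fixing
#'   the locus universe, so loci with no compatible reads report abundance
#'   0. Defaults to the loci present in `reads`.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the max absolute abundance change.
#' @return A `te_em_fit`: `abundance` (tibble `locus_id`, `abundance`,
#'   summing to the number of reads), `iterations`, `converged`, `loglik`
#'   (trace, one entry per iteration). `tidy()` returns the abundance table.
#' @export
#' @examples
#' reads <- tibble::tibble(
#'   read_id = c("r1", "r2", "r2"),
#'   locus_id = c("A", "A", "B"))
#' tidy(em_assign(reads))
em_assign <- function(reads, loci = NULL, max_iter = 200, tol = 1e-8) {
  reads <- as_tibble(reads)
  if (nrow(reads) == 0L) {
    abort("`reads` is empty; every read needs >= 1 candidate locus.",
      class = "te_input_error")
  }
  if (is.data.frame(loci)) loci <- loci$locus_id
  loci <- loci %||% sort(unique(reads$locus_id))
  if (!all(reads$locus_id %in% loci)) {
    abort("reads reference candidate loci missing from `loci`.",
      class = "te_input_error")
  }
  read_f <- factor(reads$read_id)
  locus_f <- factor(reads$locus_id, levels = loci)
  li <- as.integer(locus_f)
  ri <- as.integer(read_f)
  n_reads <- nlevels(read_f)
  n_loci <- length(loci)

  a <- rep(n_reads / n_loci, n_loci)
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    num <- a[li]
    denom <- rowsum(num, ri)[, 1]            # per-read normaliser
    w <- num / denom[ri]                      # E-step fractions
    a_new <- numeric(n_loci)
    tally <- rowsum(w, li)                    # M-step
    a_new[as.integer(rownames(tally))] <- tally[, 1]
    loglik <- c(loglik, sum(log(denom / sum(a))))
    delta <- max(abs(a_new - a))
    a <- a_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(abundance = tibble(locus_id = loci, abundance = a),
      iterations = iter, converged = converged, loglik = loglik,
      n_reads = n_reads),
    class = "te_em_fit"
  )
}

#' Restrict an expression table to full-length intact L1 loci
#'
#' Keeps only the rows of an expression table whose feature ids are in the
#' supplied intact-L1 set, isolating transcription that can only have been
#' initiated by a transposition-competent element (older fixed copies mostly
#' reflect read-through from neighbouring promoters).
#'
#' @param table Long-format expression tibble with a `feature_id` column.
#' @param intact_ids Character vector of intact-L1 feature ids; ids absent
#'   from the table are an error.
#' @return The retained rows of `table`.
#' @export
restrict_to_intact_l1 <- function(table, intact_ids) {
  unknown <- setdiff(intact_ids, unique(table$feature_id))
  if (length(unknown)) {
    abort(paste0("unknown feature ids: ",
      paste(utils::head(unknown, 5), collapse = ", ")),
      class = "te_validation_error")
  }
  table[table$feature_id %in% intact_ids, ]
}

#' Compare expression-level distributions between matched tissues
#'
#' Two-sample Kolmogorov-Smirnov test on `log10(count + pseudocount)`
#' values, a distribution-level comparison of pooled expression levels
#' rather than a per-feature differential test. The pseudocount (default 1,
#' so a zero count maps to 0 on the log10 scale) handles unexpressed
#' features.
#'
#' @param normal_counts,tumor_counts Non-empty numeric vectors of read
#'   counts (the two groups need not have equal length).
#' @param pseudocount Added before the log10 transform.
#' @return A `te_ks_test`: `statistic`, `p_value`, and the transformed
#'   `normal_log10` / `tumor_log10` vectors. `glance()` gives a one-row
#'   tibble; `autoplot()` overlays the two distributions.
#' @export
compare_expression <- function(normal_counts, tumor_counts,
                               pseudocount = 1) {
  if (length(normal_counts) == 0L || length(tumor_counts) == 0L) {
    abort("both count vectors must be non-empty.",
      class = "te_undefined_test_error")
  }
  x <- log10(normal_counts + pseudocount)
  y <- log10(tumor_counts + pseudocount)
  ks <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  structure(
    list(statistic = unname(ks$statistic), p_value = ks$p.value,
      normal_log10 = x, tumor_log10 = y, pseudocount = pseudocount,
      method = "two-sample KS on log10(count + pseudocount)"),
    class = "te_ks_test"
  )
}

#' Per-gene expression change between matched tissues
#'
#' Mean log10 tumor expression minus mean log10 normal expression per
#' feature; auxiliary input for the driver screen's concordance annotation.
#'
#' @param counts Long expression tibble: `feature_id`, `tissue`, `count`.
#' @param pseudocount Added before the log10 transform.
#' @return Tibble `gene_id`, `delta`.
#' @export
expression_delta <- function(counts, pseudocount = 1) {
  counts |>
    dplyr::group_by(.data$feature_id, .data$tissue) |>
    dplyr::summarise(m = mean(log10(.data$count + pseudocount)),
      .groups = "drop") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "m") |>
    dplyr::transmute(gene_id = .data$feature_id,
      delta = .data$tumor - .data$normal)
}
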