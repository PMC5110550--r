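# Observed-vs-expected unique-L1 enrichment and the Fisher exact test.

#' Unique-insertion count table
#'
#' Holds the per-tissue counts of unique (private) insertions for all TE
#' families combined and for L1 alone, the inputs of the L1-excess test.
#'
#' @param all_te_unique_normal,all_te_unique_tumor Unique insertions across
#'   all families in normal / tumor tissue.
#' @param l1_unique_normal,l1_unique_tumor Unique L1 insertions per tissue
#'   (each must not exceed the corresponding all-TE count).
#' @return A `te_unique_counts` object.
#' @export
unique_count_table <- function(all_te_unique_normal, all_te_unique_tumor,
                               l1_unique_normal, l1_unique_tumor) {
  vals <- c(all_te_unique_normal, all_te_unique_tumor,
    l1_unique_normal, l1_unique_tumor)
  if (any(vals < 0) || any(vals != round_half_up(vals))) {
    abort("counts must be non-negative integers.", class = "te_input_error")
  }
  if (l1_unique_normal > all_te_unique_normal ||
      l1_unique_tumor > all_te_unique_tumor) {
    abort("L1 counts cannot exceed the all-TE counts.",
      class = "te_input_error")
  }
  structure(
    list(all_te_unique_normal = all_te_unique_normal,
         all_te_unique_tumor = all_te_unique_tumor,
         l1_unique_normal = l1_unique_normal,
         l1_unique_tumor = l1_unique_tumor),
    class = "te_unique_counts"
  )
}

#' Expected unique L1 counts under family-independent tissue allocation
#'
#' The expected per-tissue L1 counts are the all-TE normal:tumor split
#' applied to the observed L1 total: `expected_normal = L1_total *
#' all_te_normal / (all_te_normal + all_te_tumor)` and analogously for
#' tumor, so the two expectations always sum to the observed L1 total.
#'
#' @param t A [unique_count_table()] with a positive all-TE total.
#' @return One-row tibble: `expected_normal`, `expected_tumor`.
#' @export
#' @examples
#' expected_l1_counts(unique_count_table(300, 390, 40, 50))
expected_l1_counts <- function(t) {
  stopifnot(inherits(t, "te_unique_counts"))
  all_total <- t$all_te_unique_normal + t$all_te_unique_tumor
  if (all_total <= 0) {
    abort("all-TE total must be positive.", class = "te_parameter_error")
  }
  l1_total <- t$l1_unique_normal + t$l1_unique_tumor
  tibble(
    expected_normal = l1_total * t$all_te_unique_normal / all_total,
    expected_tumor = l1_total * t$all_te_unique_tumor / all_total
  )
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value computed by direct enumeration of the conditional
#' hypergeometric distribution: with margins fixed, the p-value is the sum of
#' the probabilities of all tables whose probability does not exceed that of
#' the observed table (within a 1e-7 relative tolerance for floating-point
#' ties). The reported odds ratio is the sample odds ratio `(a*d)/(b*c)`.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return A `te_fisher_test` object with `estimate` (odds ratio), `p_value`
#'   and the input `table`; `p_value` lies in (0, 1]. `glance()` returns a
#'   one-row tibble.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(1, 9, 11, 3), nrow = 2, byrow = TRUE))
fisher_exact_2x2 <- function(table) {
  tbl <- as.matrix(table)
  if (!all(dim(tbl) == c(2L, 2L))) {
    abort("`table` must be 2 x 2.", class = "te_input_error")
  }
  if (any(tbl < 0) || any(tbl != round_half_up(tbl))) {
    abort("cells must be non-negative integers.", class = "te_input_error")
  }
  a <- tbl[1, 1]; b <- tbl[1, 2]; c_ <- tbl[2, 1]; d <- tbl[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  if (sum(tbl) == 0) {
    abort("at least one marginal must be positive.",
      class = "te_input_error")
  }
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) {
    # a zero marginal leaves a single attainable table
    p <- 1
  } else {
    support <- max(0, c1 - r2):min(r1, c1)
    probs <- stats::dhyper(support, r1, r2, c1)
    p_obs <- stats::dhyper(a, r1, r2, c1)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  or <- (a * d) / (b * c_)
  structure(
    list(estimate = if (is.nan(or)) NA_real_ else or, p_value = p,
      table = tbl, method = "Fisher exact (two-sided, enumeration)"),
    class = "te_fisher_test"
  )
}

#' Test for an excess of unique L1 insertions in tumor tissue
#'
#' Builds the 2 x 2 table of observed unique L1 counts (normal, tumor)
#' against their expected counts under the all-TE tissue split (rounded
#' half-up to integers, since the exact test requires integer tables) and
#' applies [fisher_exact_2x2()]. The unrounded expectations and the
#' observed/expected ratios are reported alongside. With
#' `conventional = TRUE` the conventional alternative — observed L1 vs
#' non-L1 unique counts by tissue — is tested instead.
#'
#' @param t A [unique_count_table()].
#' @param conventional Use the L1 vs non-L1 contingency instead of the
#'   observed-vs-expected construction.
#' @return A `te_l1_excess` object: `observed`, `expected` (unrounded),
#'   `expected_rounded`, `obs_over_exp` (per tissue), `odds_ratio`,
#'   `p_value`, `table`.
#' @export
l1_excess_test <- function(t, conventional = FALSE) {
  stopifnot(inherits(t, "te_unique_counts"))
  obs <- c(normal = t$l1_unique_normal, tumor = t$l1_unique_tumor)
  exp_raw <- expected_l1_counts(t)
  if (conventional) {
    tbl <- matrix(c(
      t$l1_unique_normal, t$l1_unique_tumor,
      t$all_te_unique_normal - t$l1_unique_normal,
      t$all_te_unique_tumor - t$l1_unique_tumor
    ), nrow = 2, byrow = TRUE,
      dimnames = list(c("L1", "non-L1"), c("normal", "tumor")))
  } else {
    tbl <- matrix(c(
      obs,
      round_half_up(exp_raw$expected_normal),
      round_half_up(exp_raw$expected_tumor)
    ), nrow = 2, byrow = TRUE,
      dimnames = list(c("observed", "expected"), c("normal", "tumor")))
  }
  fit <- fisher_exact_2x2(tbl)
  structure(
    list(
      observed = obs,
      expected = c(normal = exp_raw$expected_normal,
        tumor = exp_raw$expected_tumor),
      expected_rounded = c(normal = round_half_up(exp_raw$expected_normal),
        tumor = round_half_up(exp_raw$expected_tumor)),
      obs_over_exp = obs / unlist(exp_raw),
      odds_ratio = fit$estimate, p_value = fit$p_value,
      table = fit$table,
      method = if (conventional) "L1 vs non-L1 by tissue" else
        "observed vs expected unique L1 by tissue"
    ),
    class = "te_l1_excess"
  )
}
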