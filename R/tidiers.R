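# broom-style tidy()/glance() methods and compact print methods.

#' @export
glance.te_fisher_test <- function(x, ...) {
  tibble(odds_ratio = x$estimate, p_value = x$p_value, method = x$method)
}

#' @export
tidy.te_fisher_test <- function(x, ...) {
  as_tibble(as.data.frame.table(x$table, responseName = "n"))
}

#' @export
glance.te_l1_excess <- function(x, ...) {
  tibble(
    l1_unique_normal = unname(x$observed["normal"]),
    l1_unique_tumor = unname(x$observed["tumor"]),
    expected_normal = unname(x$expected["normal"]),
    expected_tumor = unname(x$expected["tumor"]),
    odds_ratio = x$odds_ratio, p_value = x$p_value, method = x$method
  )
}

#' @export
tidy.te_l1_excess <- function(x, ...) {
  tibble(
    tissue = rep(c("normal", "tumor"), 2),
    kind = rep(c("observed", "expected"), each = 2),
    count = c(x$observed, x$expected)
  )
}

#' @export
glance.te_freq_test <- function(x, ...) {
  tibble(ks_statistic = x$statistic, ks_p_value = x$p_value,
    chisq_statistic = x$chisq_statistic, chisq_p_value = x$chisq_p_value)
}

#' @export
tidy.te_freq_test <- function(x, ...) {
  tidyr::pivot_longer(x$bin_counts, c("normal", "tumor"),
    names_to = "tissue", values_to = "n")
}

#' @export
glance.te_ks_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
    n_normal = length(x$normal_log10), n_tumor = length(x$tumor_log10))
}

#' @export
tidy.te_ks_test <- function(x, ...) {
  dplyr::bind_rows(
    tibble(tissue = "normal", log10_expression = x$normal_log10),
    tibble(tissue = "tumor", log10_expression = x$tumor_log10)
  )
}

#' @export
tidy.te_em_fit <- function(x, ...) x$abundance

#' @export
glance.te_em_fit <- function(x, ...) {
  tibble(n_loci = nrow(x$abundance), n_reads = x$n_reads,
    iterations = x$iterations, converged = x$converged,
    loglik = utils::tail(x$loglik, 1))
}

#' @export
glance.te_cohort_summary <- function(x, ...) {
  tibble(total_insertions = x$total_insertions,
    unique_insertions = x$unique_insertions,
    unique_normal = x$unique_normal, unique_tumor = x$unique_tumor,
    n_patients = x$n_patients,
    shared_pct = shared_fraction(x))
}

#' @export
tidy.te_cohort_summary <- function(x, ...) {
  x$counts %||% tibble(family = character(), tissue = character(),
    n_unique = integer())
}

#' @export
print.te_fisher_test <- function(x, ...) {
  cat(x$method, "\n")
  print(x$table)
  cat(sprintf("odds ratio = %.4g, two-sided p = %.4g\n",
    x$estimate, x$p_value))
  invisible(x)
}

#' @export
print.te_l1_excess <- function(x, ...) {
  cat("Unique L1 excess test (", x$method, ")\n", sep = "")
  print(x$table)
  cat(sprintf("obs/exp: normal %.3f, tumor %.3f; p = %.4g\n",
    x$obs_over_exp[1], x$obs_over_exp[2], x$p_value))
  invisible(x)
}

#' @export
print.te_cohort_summary <- function(x, ...) {
  cat("TE cohort summary (", x$locus_convention, ")\n", sep = "")
  cat(sprintf("  total insertions: %d\n  unique (private): %d (normal %s, tumor %s)\n",
    x$total_insertions, x$unique_insertions,
    format(x$unique_normal), format(x$unique_tumor)))
  cat(sprintf("  shared fraction: %.1f%%\n", shared_fraction(x)))
  invisible(x)
}

#' @export
print.te_em_fit <- function(x, ...) {
  cat(sprintf("EM read assignment: %d loci, %d reads, %d iterations (%s)\n",
    nrow(x$abundance), x$n_reads, x$iterations,
    if (x$converged) "converged" else "max_iter reached"))
  print(x$abundance)
  invisible(x)
}
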