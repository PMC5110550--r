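panel_tbl <- function(pos, af, family = "L1", chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos),
    family = rep_len(family, length(pos)), af = af)
}

ins_tbl <- function(pos, family = "L1", chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos),
    family = rep_len(family, length(pos)))
}

test_that("frequency bins follow the 0.05 threshold with a closed high bin", {
  panel <- panel_tbl(c(1010, 5000, 9000), c(0.30, 0.01, 0.05))
  ann <- annotate_frequencies(ins_tbl(c(1000, 5020, 9010, 20000)), panel)
  expect_equal(as.character(ann$bin), c("high", "low", "high", "private"))
  expect_equal(ann$panel_af, c(0.30, 0.01, 0.05, NA))

  # the documented flag flips the boundary case to the low bin
  ann2 <- annotate_frequencies(ins_tbl(9010), panel, high_closed = FALSE)
  expect_equal(as.character(ann2$bin), "low")
})

test_that("matching requires same family within the window, nearest wins", {
  panel <- rbind(panel_tbl(c(980, 1030), c(0.2, 0.6)),
    panel_tbl(1000, 0.9, family = "Alu"))
  ann <- annotate_frequencies(ins_tbl(1000), panel)
  expect_equal(ann$panel_pos, 980L)  # distance 20 beats 30; Alu ignored
  # beyond 100 bp: private
  ann2 <- annotate_frequencies(ins_tbl(1200), panel)
  expect_equal(as.character(ann2$bin), "private")
  expect_error(annotate_frequencies(ins_tbl(1000), panel_tbl(1000, 1.2)),
    class = "te_panel_error")
})

test_that("annotation is idempotent and independent of input order", {
  set.seed(91)
  panel <- panel_tbl(seq(1000, by = 700, length.out = 30),
    runif(30, 0.001, 1))
  ins <- ins_tbl(seq(1020, by = 700, length.out = 30))
  ann <- annotate_frequencies(ins, panel)
  shuf <- sample(nrow(ins))
  ann_shuf <- annotate_frequencies(ins[shuf, ], panel)
  expect_equal(ann_shuf[order(shuf), ]$bin, ann$bin)
  ann_again <- annotate_frequencies(ann[, c("chrom", "pos", "family")],
    panel)
  expect_equal(ann_again$bin, ann$bin)
})

test_that("every annotated insertion falls in exactly one bin", {
  cohort <- simulate_cohort(cohort_config(n_patients = 2, seed = 44))
  cons <- analyze_cohort(cohort)$consensus
  ann <- annotate_frequencies(cons, cohort$panel)
  expect_false(any(is.na(ann$bin)))
  expect_true(all((as.character(ann$bin) == "private") == is.na(ann$panel_af)))
})

test_that("somatic truth insertions are always private; germline mostly not", {
  cfg <- cohort_config(n_patients = 3, caller_fp_rate = 0,
    caller_fn_rate = 0, caller_jitter_sd = 0, seed = 12)
  cohort <- simulate_cohort(cfg)
  calls <- cohort$calls[cohort$calls$caller_id == "caller_a", ]
  ann <- annotate_frequencies(calls, cohort$panel)
  som <- ann[grepl("^S", ann$truth_locus_id), ]
  germ <- ann[grepl("^G", ann$truth_locus_id), ]
  expect_true(all(as.character(som$bin) == "private"))
  expect_true(all(as.character(germ$bin) != "private"))
})

test_that("KS comparison behaves on identical and disjoint annotations", {
  panel <- panel_tbl(1000, 0.5)
  high <- annotate_frequencies(ins_tbl(rep(1000, 6)), panel)
  priv <- annotate_frequencies(ins_tbl(rep(50000, 6)), panel)
  same <- compare_bin_distributions(high, high)
  expect_equal(same$statistic, 0)
  expect_gt(same$p_value, 0.99)
  opp <- compare_bin_distributions(high, priv)
  expect_equal(opp$statistic, 1)
  expect_error(compare_bin_distributions(high[0, ], priv),
    class = "te_undefined_test_error")
})

test_that("KS statistic equals the brute-force ECDF gap on small samples", {
  set.seed(14)
  panel <- panel_tbl(seq(1000, by = 700, length.out = 8),
    c(0.02, 0.2, 0.5, 0.04, 0.9, 0.01, 0.06, 0.3))
  for (rep in 1:10) {
    nx <- sample(2:8, 1)
    ny <- sample(2:8, 1)
    x <- annotate_frequencies(
      ins_tbl(sample(c(panel$pos, 90000), nx, replace = TRUE)), panel)
    y <- annotate_frequencies(
      ins_tbl(sample(c(panel$pos, 90000), ny, replace = TRUE)), panel)
    res <- compare_bin_distributions(x, y)
    expect_equal(res$statistic,
      oracle_ks_stat(res$normal_af, res$tumor_af), tolerance = 1e-12)
  }
})

test_that("bin-count table is complete and the companion chi-square runs", {
  panel <- panel_tbl(c(1000, 2000), c(0.5, 0.01))
  norm <- annotate_frequencies(ins_tbl(c(1000, 1000, 2000, 90000)), panel)
  tum <- annotate_frequencies(ins_tbl(c(90000, 91000, 2000)), panel)
  res <- compare_bin_distributions(norm, tum)
  expect_equal(sort(as.character(res$bin_counts$bin)),
    sort(c("private", "low", "high")))
  expect_equal(sum(res$bin_counts$normal), 4L)
  expect_equal(sum(res$bin_counts$tumor), 3L)
  expect_true(res$chisq_p_value >= 0 && res$chisq_p_value <= 1)
})
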