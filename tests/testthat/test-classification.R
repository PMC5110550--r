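consensus_row <- function(pos, family = "Alu", chrom = "chr2",
                          support = 20L, sample = "P01.normal") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos),
    family = rep_len(family, length(pos)),
    support_reads = as.integer(rep_len(support, length(pos))),
    sample_id = sample, tissue = sub("^.*\\.", "", sample))
}

test_that("tissue pairing classifies shared and tissue-specific insertions", {
  prof <- pair_tissues(consensus_row(500), consensus_row(560,
    sample = "P01.tumor"))
  expect_equal(prof$status, "shared")
  expect_equal(prof$pos, 530L)

  prof2 <- pair_tissues(consensus_row(500), consensus_row(integer(),
    sample = "P01.tumor"))
  expect_equal(prof2$status, "normal_only")

  # beyond the window: two tissue-specific records, not one shared
  prof3 <- pair_tissues(consensus_row(500), consensus_row(700,
    sample = "P01.tumor"))
  expect_setequal(prof3$status, c("normal_only", "tumor_only"))
  expect_error(pair_tissues(consensus_row(500),
    consensus_row(560, sample = "P02.tumor")), class = "te_input_error")
})

test_that("the three status classes partition each patient's loci", {
  set.seed(29)
  for (rep in 1:5) {
    sc <- random_spaced_scenario(25)
    normal <- dplyr::mutate(sc$a, sample_id = "P01.normal",
      tissue = "normal")
    tumor <- dplyr::mutate(sc$b, sample_id = "P01.tumor", tissue = "tumor")
    prof <- pair_tissues(normal, tumor)
    n_shared <- sum(prof$status == "shared")
    expect_equal(nrow(prof), nrow(normal) + nrow(tumor) - n_shared)
    expect_equal(sum(prof$status == "normal_only"),
      nrow(normal) - n_shared)
    expect_equal(sum(prof$status == "tumor_only"), nrow(tumor) - n_shared)
  }
})

test_that("cross-patient recurrence disqualifies private status", {
  p1 <- pair_tissues(consensus_row(integer(), chrom = "chr3",
    sample = "P01.normal"),
    consensus_row(1000, family = "L1", chrom = "chr3",
      sample = "P01.tumor"))
  p2 <- pair_tissues(consensus_row(integer(), chrom = "chr3",
    sample = "P02.normal"),
    consensus_row(1040, family = "L1", chrom = "chr3",
      sample = "P02.tumor"))
  s <- find_private_insertions(rbind(p1, p2))
  expect_equal(s$unique_insertions, 0L)

  # a single-patient tumor-only call is private
  s1 <- find_private_insertions(p1)
  expect_equal(s1$unique_insertions, 1L)
  expect_equal(s1$unique_tumor, 1L)

  # different family at the same position does not disqualify
  p3 <- pair_tissues(consensus_row(integer(), chrom = "chr3",
    sample = "P03.normal"),
    consensus_row(1040, family = "Alu", chrom = "chr3",
      sample = "P03.tumor"))
  s2 <- find_private_insertions(rbind(p1, p3))
  expect_equal(s2$unique_insertions, 2L)
})

test_that("summary arithmetic reproduces the published cohort figures", {
  s <- cohort_summary(total_insertions = 3672, unique_insertions = 693,
    unique_normal = 300, unique_tumor = 393)
  expect_equal(average_private_per_patient(s, n_patients = 9), 77)
  expect_equal(shared_fraction(s), 81.1)
  expect_equal(round(tissue_excess_ratio(s), 2), 1.31)
})

test_that("summary operations handle edge cases and errors", {
  expect_equal(average_private_per_patient(cohort_summary(10, 0),
    n_patients = 3), 0)
  expect_equal(average_private_per_patient(cohort_summary(100, 90),
    n_patients = 9), 10)
  expect_equal(shared_fraction(cohort_summary(10, 0)), 100.0)
  expect_equal(shared_fraction(cohort_summary(10, 5)), 50.0)
  expect_error(average_private_per_patient(cohort_summary(10, 5),
    n_patients = 0), class = "te_parameter_error")
  expect_error(shared_fraction(cohort_summary(0, 0)),
    class = "te_parameter_error")
  expect_error(cohort_summary(5, 10), class = "te_input_error")
})

test_that("an error-free cohort is classified back to truth exactly", {
  cfg <- cohort_config(n_patients = 3, caller_fp_rate = 0,
    caller_fn_rate = 0, caller_jitter_sd = 0, support_real_size = 1000,
    seed = 21)
  cohort <- simulate_cohort(cfg)
  res <- analyze_cohort(cohort)

  # shared set = germline truth occurrences of each patient
  germ <- cohort$truth$loci[cohort$truth$loci$origin == "germline", ]
  germ_occ <- dplyr::inner_join(cohort$truth$carriers,
    germ[, c("locus_id", "chrom", "pos")], by = "locus_id") |>
    dplyr::filter(tissue == "normal")
  shared <- res$profiles[res$profiles$status == "shared", ]
  expect_identical(
    sort(paste(shared$patient_id, shared$chrom, shared$pos)),
    sort(paste(germ_occ$patient_id, germ_occ$chrom, germ_occ$pos)))

  # private set = somatic truth exactly
  expect_equal(res$score$precision, 1)
  expect_equal(res$score$recall, 1)
  som <- cohort$truth$loci[cohort$truth$loci$origin == "somatic", ]
  expect_equal(res$summary$unique_insertions, nrow(som))
})
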