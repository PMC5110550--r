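test_that("invalid configurations are rejected", {
  expect_error(cohort_config(genome = tibble::tibble(chrom = "chr1",
    length = -5)), class = "te_config_error")
  expect_error(cohort_config(families = character()),
    class = "te_config_error")
  expect_error(cohort_config(tumor_l1_multiplier = 0.5),
    class = "te_config_error")
  expect_error(cohort_config(caller_fn_rate = 1.2),
    class = "te_config_error")
})

test_that("identical config and seed give identical cohorts", {
  cfg <- cohort_config(n_patients = 2, seed = 123)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$truth$loci, c2$truth$loci)
  expect_identical(c1$calls, c2$calls)
  expect_identical(c1$expression, c2$expression)
  c3 <- simulate_cohort(cohort_config(n_patients = 2, seed = 124))
  expect_false(identical(c1$calls, c3$calls))
})

test_that("germline truth records carry both tissues; somatic exactly one", {
  truth <- simulate_truth(cohort_config(n_patients = 4, seed = 2))
  germ <- truth$loci[truth$loci$origin == "germline", ]
  som <- truth$loci[truth$loci$origin == "somatic", ]
  germ_carr <- truth$carriers[truth$carriers$locus_id %in% germ$locus_id, ]
  per <- dplyr::count(germ_carr, locus_id, patient_id)
  expect_true(all(per$n == 2L))  # both tissues per carrier patient
  som_carr <- truth$carriers[truth$carriers$locus_id %in% som$locus_id, ]
  expect_equal(nrow(som_carr), nrow(som))  # one tissue of one patient
  expect_true(all(is.na(som$panel_af)))
  expect_true(all(!is.na(germ$panel_af)))
})

test_that("panel holds exactly the germline loci plus the configured extras", {
  cfg <- cohort_config(n_patients = 2, n_panel_extra = 40, seed = 9)
  truth <- simulate_truth(cfg)
  germ <- truth$loci[truth$loci$origin == "germline", ]
  expect_equal(nrow(truth$panel), nrow(germ) + 40L)
  key <- function(d) paste(d$chrom, d$pos)
  expect_true(all(key(germ) %in% key(truth$panel)))
  # no somatic locus ever enters the panel
  som <- truth$loci[truth$loci$origin == "somatic", ]
  expect_false(any(key(som) %in% key(truth$panel)))
})

test_that("all simulated loci respect the minimum spacing", {
  truth <- simulate_truth(cohort_config(n_patients = 3, seed = 31))
  all_pos <- rbind(truth$loci[, c("chrom", "pos")],
    truth$fp_pool[, c("chrom", "pos")])
  gaps <- all_pos |>
    dplyr::arrange(chrom, pos) |>
    dplyr::group_by(chrom) |>
    dplyr::summarise(min_gap = min(diff(pos)), .groups = "drop")
  expect_true(all(gaps$min_gap >= 500))
})

test_that("degenerate rates yield germline-only calls, identical across tissues", {
  cfg <- cohort_config(n_patients = 2, somatic_rate_normal = 0,
    somatic_rate_tumor = 0, caller_fp_rate = 0, caller_fn_rate = 0,
    caller_jitter_sd = 0, seed = 77)
  cohort <- simulate_cohort(cfg)
  expect_true(all(!cohort$calls$is_fp))
  germ_ids <- cohort$truth$loci$locus_id[
    cohort$truth$loci$origin == "germline"]
  expect_true(all(cohort$calls$truth_locus_id %in% germ_ids))
  a <- cohort$calls[cohort$calls$caller_id == "caller_a" &
    cohort$calls$patient_id == "P01", ]
  expect_identical(
    sort(a$pos[a$tissue == "normal"]), sort(a$pos[a$tissue == "tumor"]))
})

test_that("error-free calls reproduce the truth occurrences exactly", {
  cfg <- cohort_config(n_patients = 2, caller_fp_rate = 0,
    caller_fn_rate = 0, caller_jitter_sd = 0, seed = 15)
  cohort <- simulate_cohort(cfg)
  occ <- dplyr::inner_join(cohort$truth$carriers,
    cohort$truth$loci[, c("locus_id", "chrom", "pos")], by = "locus_id")
  for (cid in c("caller_a", "caller_b")) {
    calls <- cohort$calls[cohort$calls$caller_id == cid, ]
    expect_equal(nrow(calls), nrow(occ))
    expect_identical(
      sort(paste(calls$patient_id, calls$tissue, calls$chrom, calls$pos)),
      sort(paste(occ$patient_id, occ$tissue, occ$chrom, occ$pos)))
  }
})

test_that("tumor somatic L1 excess follows the configured multiplier", {
  cfg <- cohort_config(n_patients = 9, tumor_l1_multiplier = 2, seed = 8)
  truth <- simulate_truth(cfg)
  som <- truth$loci[truth$loci$origin == "somatic" &
    truth$loci$family == "L1", ]
  n_t <- sum(som$tissue == "tumor")
  n_n <- sum(som$tissue == "normal")
  # Poisson expectations at the configured rates
  lam_n <- cfg$somatic_rate_normal * cfg$n_patients
  lam_t <- lam_n * cfg$tumor_l1_multiplier
  expect_lt(abs(n_n - lam_n), 3 * sqrt(lam_n))
  expect_lt(abs(n_t - lam_t), 3 * sqrt(lam_t))
})

test_that("panel allele frequencies match the configured Beta distribution", {
  cfg <- cohort_config(n_patients = 1, n_germline_loci = 1500,
    n_panel_extra = 0, seed = 55)
  truth <- simulate_truth(cfg)
  gof <- suppressWarnings(stats::ks.test(truth$panel$af, stats::pbeta,
    cfg$germline_af_shape1, cfg$germline_af_shape2))
  expect_gt(gof$p.value, 0.01)
})

test_that("noise-component mass below the 5-read threshold is recoverable", {
  cfg <- cohort_config(n_patients = 4, caller_fp_rate = 0.3, seed = 60)
  cohort <- simulate_cohort(cfg)
  fp <- cohort$calls[cohort$calls$is_fp, ]
  observed <- mean(fp$support_reads < 5)
  expected <- stats::pnbinom(4, mu = cfg$support_noise_mean,
    size = cfg$support_noise_size)
  se <- sqrt(expected * (1 - expected) / nrow(fp))
  expect_lt(abs(observed - expected), 4 * se)
})

test_that("truth tables round-trip losslessly and count rows faithfully", {
  dir <- withr::local_tempdir()
  truth <- simulate_truth(cohort_config(n_patients = 2, seed = 3))
  write_truth_tables(truth, dir)
  back <- read_truth_tables(dir)
  expect_equal(nrow(back$loci), nrow(truth$loci))
  expect_equal(as.data.frame(back$loci), as.data.frame(truth$loci))

  # empty truth set: header-only files
  empty <- truth
  empty$loci <- truth$loci[0, ]
  empty$carriers <- truth$carriers[0, ]
  write_truth_tables(empty, dir)
  expect_equal(nrow(read_truth_tables(dir)$loci), 0L)
})
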