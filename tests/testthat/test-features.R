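# a compact hand-built feature bundle:
# GENE_A chr1 [1000, 9000) + strand, exons [1000,1500) and [8000,9000)
# GENE_B chr1 [20000, 30000) - strand, exon [24000,25000)
# enhancer chr1 [480, 700); enhancer chr1 [8100, 8300) (inside GENE_A exon)
tiny_features <- function(tsg = "GENE_A") {
  feature_bundle(
    genes = tibble::tibble(
      gene_id = c("GENE_A", "GENE_B"), chrom = "chr1",
      strand = c("+", "-"), tx_start = c(1000, 20000),
      tx_end = c(9000, 30000)),
    exons = tibble::tibble(
      gene_id = c("GENE_A", "GENE_A", "GENE_B"), chrom = "chr1",
      start = c(1000, 8000, 24000), end = c(1500, 9000, 25000)),
    enhancers = tibble::tibble(chrom = "chr1", start = c(480, 8100),
      end = c(700, 8300)),
    tumor_suppressors = tsg
  )
}

test_that("context classification follows the documented precedence", {
  f <- tiny_features()
  ins <- tibble::tibble(chrom = "chr1",
    pos = c(1200L,   # exon of GENE_A
            5000L,   # transcript span, no exon/enhancer -> intronic
            600L,    # enhancer upstream of GENE_A -> regulatory
            8200L,   # exon AND enhancer -> exonic wins
            50000L)) # nothing -> intergenic
  res <- classify_contexts(ins, f)
  expect_equal(as.character(res$context),
    c("exonic", "intronic", "regulatory", "exonic", "intergenic"))
  expect_equal(res$gene_id, c("GENE_A", "GENE_A", NA, "GENE_A", NA))
})

test_that("half-open interval arithmetic is respected at the boundaries", {
  f <- tiny_features()
  # exon [1000, 1500): 0-based 1000 is 1-based 1001; 0-based 1500 is outside
  # pos 1501 -> 0-based 1500: first base past the exon, still genic
  # pos 1000 -> 0-based 999: just upstream of the transcript start
  res <- classify_contexts(tibble::tibble(chrom = "chr1",
    pos = c(1001L, 1501L, 1000L)), f)
  expect_equal(as.character(res$context),
    c("exonic", "intronic", "intergenic"))
})

test_that("classification agrees with a brute-force feature scan", {
  set.seed(19)
  for (rep in 1:5) {
    cfg <- cohort_config(n_patients = 1, seed = 100 + rep,
      features = list(n_genes = 40, n_enhancers = 25))
    f <- simulate_features(cfg)
    ins <- tibble::tibble(
      chrom = sample(cfg$genome$chrom, 60, replace = TRUE),
      pos = sample.int(3e7, 60))
    res <- classify_contexts(ins, f)
    expected <- mapply(oracle_context, ins$chrom, ins$pos,
      MoreArgs = list(features = f))
    expect_equal(as.character(res$context), unname(expected))
  }
})

test_that("feature validation rejects malformed bundles", {
  expect_error(feature_bundle(
    genes = tibble::tibble(gene_id = "G", chrom = "chr1", strand = "+",
      tx_start = 100, tx_end = 50),
    exons = tibble::tibble(gene_id = character(), chrom = character(),
      start = numeric(), end = numeric()),
    enhancers = tibble::tibble(chrom = character(), start = numeric(),
      end = numeric()),
    tumor_suppressors = character()), class = "te_validation_error")
  expect_error(feature_bundle(
    genes = tibble::tibble(gene_id = "G", chrom = "chr1", strand = "+",
      tx_start = 100, tx_end = 500),
    exons = tibble::tibble(gene_id = "G", chrom = "chr1",
      start = 90, end = 200),  # exon leaks out of the span
    enhancers = tibble::tibble(chrom = character(), start = numeric(),
      end = numeric()),
    tumor_suppressors = character()), class = "te_validation_error")
})

test_that("context summaries reproduce published-style percentages", {
  labels <- tibble::tibble(context = rep(
    c("intergenic", "intronic", "exonic"), c(141, 246, 6)))
  s <- summarize_contexts(labels)
  expect_equal(sum(s$n), 393L)
  expect_equal(s$pct[s$context == "intergenic"], 35.9)
  expect_equal(s$pct[s$context == "intronic"], 62.6)
  expect_equal(s$pct[s$context == "exonic"], 1.5)
  expect_equal(nrow(summarize_contexts(labels[0, , drop = FALSE])), 0L)
})

test_that("driver flagging screens tumor-suppressor exons and enhancers", {
  f <- tiny_features(tsg = "GENE_A")
  ins <- tibble::tibble(chrom = "chr1",
    pos = c(1200L, 600L, 24500L, 50000L),
    family = c("L1", "Alu", "L1", "SVA"))
  labels <- classify_contexts(ins, f)
  delta <- tibble::tibble(gene_id = c("GENE_A", "GENE_B"),
    delta = c(-1.5, 0.4))
  cand <- flag_candidate_drivers(labels, f, expression_delta = delta)
  # exonic L1 in GENE_A and the regulatory Alu linked to GENE_A's TSS;
  # GENE_B exon is excluded (not a tumor suppressor), intergenic excluded
  expect_equal(nrow(cand), 2L)
  expect_setequal(cand$linked_gene, "GENE_A")
  expect_true(all(cand$concordance == "concordant"))

  # up-regulated gene: candidates remain but are discordant
  cand2 <- flag_candidate_drivers(labels, f,
    expression_delta = tibble::tibble(gene_id = "GENE_A", delta = 0.7))
  expect_true(all(cand2$concordance == "discordant"))

  # with a zero TSS cap no regulatory insertion ever links to a gene
  cand3 <- flag_candidate_drivers(labels, f, tss_cap = 0)
  expect_equal(as.character(cand3$context), "exonic")
})

test_that("shared (germline) insertions are screened out upstream", {
  # the screen operates on tumor-private labels only: a germline insertion
  # in a tumor-suppressor exon is simply never passed in
  f <- tiny_features()
  private_only <- classify_contexts(tibble::tibble(chrom = "chr1",
    pos = 600L, family = "Alu"), f)
  cand <- flag_candidate_drivers(private_only, f)
  expect_equal(nrow(cand), 1L)
  expect_equal(as.character(cand$context), "regulatory")
})
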