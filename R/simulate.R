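# Synthetic cohort generation: truth loci, emulated caller output, reference
# panel, genome features and expression tables for matched normal/tumor pairs.

# Well-separated genomic positions. Slots live on a grid of step
# (spacing + 100) with a uniform 0-99 bp offset, so any two distinct slots are
# >= spacing + 1 bp apart. This guarantees the +/-100 bp merge window can
# never fuse two distinct truth loci, and false-positive calls drawn from
# unused slots are always >= spacing bp from every truth locus.
draw_position_pool <- function(genome, n, spacing) {
  step <- spacing + 100
  capacity <- pmax(floor((genome$length - 200) / step), 0L)
  if (sum(capacity) < n) {
    abort("genome too small for the requested number of separated loci.",
      class = "te_config_error")
  }
  n_chrom <- stats::rmultinom(1, n, prob = capacity)[, 1]
  out <- purrr::map2(seq_len(nrow(genome)), n_chrom, function(i, k) {
    if (k == 0) return(NULL)
    idx <- sort(sample.int(capacity[i], k))
    tibble(
      chrom = genome$chrom[i],
      pos = (idx - 1L) * step + 100L +
        sample.int(100L, k, replace = TRUE)
    )
  })
  dplyr::bind_rows(out)[sample.int(n), ]
}

patient_ids <- function(n) sprintf("P%02d", seq_len(n))

#' Simulate the truth layer of a synthetic TE cohort
#'
#' Draws the germline and somatic insertion truth set and the population
#' reference panel, without emulating caller behaviour. Germline loci receive
#' Beta-distributed population allele frequencies and are carried by a patient
#' (in both tissues) with the diploid carrier probability `1 - (1 - af)^2`;
#' somatic loci are private to one tissue of one patient, arise at the
#' configured Poisson rates, and are never placed in the panel. The panel
#' contains every germline locus with its allele frequency plus
#' `n_panel_extra` loci carried by no patient.
#'
#' @param config A [cohort_config()].
#' @return A `te_truth` list with elements `loci` (tibble: `locus_id`,
#'   `chrom`, `pos`, `family`, `origin`, `panel_af`, `patient_id`, `tissue`;
#'   the last two are `NA` for germline records), `carriers` (tibble:
#'   `locus_id`, `patient_id`, `tissue`) and `panel` (tibble: `chrom`, `pos`,
#'   `family`, `af`).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "te_cohort_config"))
  cfg <- config
  pats <- patient_ids(cfg$n_patients)
  fam_w <- cfg$family_weights[cfg$families]

  # stage 1: somatic event counts (needed to size the position pool)
  set.seed(child_seed(cfg$seed, 1))
  grid <- tidyr::expand_grid(
    patient_id = pats, tissue = cfg$tissues, family = cfg$families
  )
  grid$rate <- ifelse(grid$tissue == "tumor",
    cfg$somatic_rate_tumor, cfg$somatic_rate_normal)
  grid$rate <- ifelse(grid$tissue == "tumor" & grid$family == "L1",
    grid$rate * cfg$tumor_l1_multiplier, grid$rate)
  grid$n <- stats::rpois(nrow(grid), grid$rate)
  n_somatic <- sum(grid$n)

  # stage 2: positions for all loci plus a slack pool for false positives
  set.seed(child_seed(cfg$seed, 2))
  exp_true_calls <- cfg$n_germline_loci + n_somatic / max(cfg$n_patients, 1)
  fp_slack <- ceiling(4 * cfg$caller_fp_rate * exp_true_calls *
                        2 * cfg$n_patients * 2) + 200
  n_pool <- cfg$n_germline_loci + cfg$n_panel_extra + n_somatic + fp_slack
  pool <- draw_position_pool(cfg$genome, n_pool, cfg$min_locus_spacing)

  take <- local({
    i <- 0L
    function(k) {
      rows <- pool[i + seq_len(k), , drop = FALSE]
      i <<- i + k
      rows
    }
  })

  # stage 3: germline loci, allele frequencies, carriers
  set.seed(child_seed(cfg$seed, 3))
  germ <- take(cfg$n_germline_loci)
  germ$locus_id <- sprintf("G%05d", seq_len(nrow(germ)))
  germ$family <- sample(cfg$families, nrow(germ), replace = TRUE,
    prob = fam_w)
  germ$origin <- "germline"
  germ$panel_af <- stats::rbeta(nrow(germ),
    cfg$germline_af_shape1, cfg$germline_af_shape2)
  # AFs of zero are not representable in a panel of observed polymorphisms
  germ$panel_af <- pmin(pmax(germ$panel_af, 1e-4), 1)

  carrier_p <- 1 - (1 - germ$panel_af)^2
  carr <- tidyr::expand_grid(locus_id = germ$locus_id, patient_id = pats)
  carr$p <- rep(carrier_p, each = cfg$n_patients)
  carr <- carr[stats::runif(nrow(carr)) < carr$p, c("locus_id", "patient_id")]
  germ_carriers <- tidyr::expand_grid(
    carr, tissue = cfg$tissues
  )

  extra <- take(cfg$n_panel_extra)
  if (nrow(extra)) {
    extra$family <- sample(cfg$families, nrow(extra), replace = TRUE,
      prob = fam_w)
    extra$af <- pmin(pmax(stats::rbeta(nrow(extra),
      cfg$germline_af_shape1, cfg$germline_af_shape2), 1e-4), 1)
  }

  # stage 4: somatic loci, private to one tissue of one patient
  set.seed(child_seed(cfg$seed, 4))
  som <- grid[rep(seq_len(nrow(grid)), grid$n),
              c("patient_id", "tissue", "family")]
  som <- dplyr::bind_cols(take(nrow(som)), som)
  som$locus_id <- sprintf("S%05d", seq_len(nrow(som)))
  som$origin <- rep("somatic", nrow(som))
  som$panel_af <- rep(NA_real_, nrow(som))

  loci <- dplyr::bind_rows(
    dplyr::mutate(germ, patient_id = NA_character_, tissue = NA_character_),
    som
  ) |>
    dplyr::select("locus_id", "chrom", "pos", "family", "origin",
                  "panel_af", "patient_id", "tissue")
  carriers <- dplyr::bind_rows(
    germ_carriers,
    som[, c("locus_id", "patient_id", "tissue")]
  ) |> dplyr::arrange(.data$locus_id, .data$patient_id, .data$tissue)

  panel <- dplyr::bind_rows(
    germ[, c("chrom", "pos", "family", "panel_af")] |>
      dplyr::rename(af = "panel_af"),
    if (nrow(extra)) extra[, c("chrom", "pos", "family", "af")]
  ) |> dplyr::arrange(.data$chrom, .data$pos)

  structure(
    list(loci = as_tibble(loci), carriers = as_tibble(carriers),
         panel = as_tibble(panel),
         fp_pool = as_tibble(take(fp_slack)), config = cfg),
    class = "te_truth"
  )
}

#' Emulate two TE insertion callers on a truth set
#'
#' Produces per-caller call tables for every sample. True insertions are
#' missed with probability `caller_fn_rate`, reported with rounded-Gaussian
#' positional jitter truncated at +/- 100 bp, and given negative-binomial
#' supporting-read counts centred on the sample's mean depth. False positives
#' arise at `caller_fp_rate` per true call, are placed on unused well-spaced
#' positions (>= `min_locus_spacing` bp from any truth locus) and draw their
#' support from the low-mean noise component, producing the bimodal support
#' distribution the read-count filter targets.
#'
#' @param truth A `te_truth` from [simulate_truth()].
#' @param config A [cohort_config()]; defaults to the one stored in `truth`.
#' @param caller_ids Identifiers of the two emulated callers.
#' @return Tibble of calls: `chrom`, `pos`, `family`, `support_reads`,
#'   `caller_id`, `patient_id`, `tissue`, `sample_id`, `truth_locus_id`
#'   (`NA` for false positives), `is_fp`.
#' @export
simulate_calls <- function(truth, config = truth$config,
                           caller_ids = c("caller_a", "caller_b")) {
  stopifnot(inherits(truth, "te_truth"), length(caller_ids) == 2L)
  cfg <- config
  occ <- dplyr::inner_join(truth$carriers, truth$loci[
    , c("locus_id", "chrom", "pos", "family")], by = "locus_id")
  fp_pool <- truth$fp_pool
  fp_cursor <- 0L

  out <- vector("list", length(caller_ids))
  for (ci in seq_along(caller_ids)) {
    set.seed(child_seed(cfg$seed, 10 + ci))
    det <- occ[stats::runif(nrow(occ)) >= cfg$caller_fn_rate, ]
    jit <- round(stats::rnorm(nrow(det), 0, cfg$caller_jitter_sd))
    jit <- pmax(-100, pmin(100, jit))
    det$pos <- pmax(1L, det$pos + as.integer(jit))
    det$support_reads <- stats::rnbinom(nrow(det),
      mu = cfg$mean_depth, size = cfg$support_real_size)
    det$is_fp <- FALSE

    # false positives, per sample
    samples <- tidyr::expand_grid(patient_id = patient_ids(cfg$n_patients),
                                  tissue = cfg$tissues)
    n_true <- dplyr::count(det, .data$patient_id, .data$tissue)
    samples <- dplyr::left_join(samples, n_true,
      by = c("patient_id", "tissue"))
    samples$n <- tidyr::replace_na(samples$n, 0L)
    samples$n_fp <- stats::rpois(nrow(samples), cfg$caller_fp_rate * samples$n)
    n_fp <- sum(samples$n_fp)
    if (n_fp > nrow(fp_pool) - fp_cursor) {
      abort("false-positive position pool exhausted; regenerate with a larger genome.",
        class = "te_config_error")
    }
    fp <- fp_pool[fp_cursor + seq_len(n_fp), ]
    fp_cursor <- fp_cursor + n_fp
    if (n_fp) {
      fp$patient_id <- rep(samples$patient_id, samples$n_fp)
      fp$tissue <- rep(samples$tissue, samples$n_fp)
      fp$family <- sample(cfg$families, n_fp, replace = TRUE,
        prob = cfg$family_weights[cfg$families])
      fp$support_reads <- stats::rnbinom(n_fp,
        mu = cfg$support_noise_mean, size = cfg$support_noise_size)
      fp$locus_id <- NA_character_
      fp$is_fp <- TRUE
    }

    calls <- dplyr::bind_rows(det, fp)
    calls$caller_id <- caller_ids[ci]
    out[[ci]] <- calls
  }

  dplyr::bind_rows(out) |>
    dplyr::mutate(
      sample_id = paste(.data$patient_id, .data$tissue, sep = "."),
      truth_locus_id = .data$locus_id
    ) |>
    dplyr::select("chrom", "pos", "family", "support_reads", "caller_id",
                  "patient_id", "tissue", "sample_id", "truth_locus_id",
                  "is_fp") |>
    dplyr::arrange(.data$caller_id, .data$sample_id, .data$chrom, .data$pos)
}

#' Simulate gene models, enhancers and a tumor-suppressor list
#'
#' Gene models are non-overlapping spans with 0-based half-open exon
#' intervals nested inside them; enhancers are short intervals placed
#' uniformly on the genome; the tumor-suppressor list is a random subset of
#' gene ids (emulating a curated cancer-gene catalogue).
#'
#' @inheritParams simulate_calls
#' @return A [feature_bundle()].
#' @export
simulate_features <- function(config) {
  stopifnot(inherits(config, "te_cohort_config"))
  cfg <- config
  fp <- cfg$features
  set.seed(child_seed(cfg$seed, 20))

  step <- fp$gene_span + 1000
  capacity <- pmax(floor(cfg$genome$length / step) - 1L, 0L)
  if (sum(capacity) < fp$n_genes) {
    abort("genome too small for the requested gene count.",
      class = "te_config_error")
  }
  n_chrom <- stats::rmultinom(1, fp$n_genes, prob = capacity)[, 1]
  genes <- purrr::map2(seq_len(nrow(cfg$genome)), n_chrom, function(i, k) {
    if (k == 0) return(NULL)
    idx <- sort(sample.int(capacity[i], k))
    tibble(chrom = cfg$genome$chrom[i], tx_start = (idx - 1L) * step)
  }) |> dplyr::bind_rows()
  genes$gene_id <- sprintf("GENE%04d", seq_len(nrow(genes)))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes$tx_start <- as.integer(genes$tx_start)
  genes$tx_end <- as.integer(genes$tx_start + fp$gene_span)
  genes <- genes[, c("gene_id", "chrom", "strand", "tx_start", "tx_end")]

  n_ex <- sample(seq(fp$exons_per_gene[1], fp$exons_per_gene[2]),
    nrow(genes), replace = TRUE)
  exons <- genes[rep(seq_len(nrow(genes)), n_ex), c("gene_id", "chrom")]
  chunk_i <- unlist(lapply(n_ex, seq_len))
  chunk_n <- rep(n_ex, n_ex)
  tx0 <- rep(genes$tx_start, n_ex)
  chunk_w <- floor(fp$gene_span / chunk_n)
  ex_w <- pmin(150L + stats::rgeom(length(chunk_i), 1 / 800),
    chunk_w - 10L)
  ex_off <- floor(stats::runif(length(chunk_i)) * (chunk_w - ex_w))
  exons$start <- as.integer(tx0 + (chunk_i - 1L) * chunk_w + ex_off)
  exons$end <- as.integer(exons$start + ex_w)

  enh <- tibble(
    chrom = sample(cfg$genome$chrom, fp$n_enhancers, replace = TRUE,
      prob = cfg$genome$length),
    start = NA_real_
  )
  len <- cfg$genome$length[match(enh$chrom, cfg$genome$chrom)]
  enh$start <- as.integer(floor(stats::runif(fp$n_enhancers) *
    (len - fp$enhancer_width)))
  enh$end <- as.integer(enh$start + fp$enhancer_width)
  enh <- dplyr::arrange(enh, .data$chrom, .data$start)

  tsg <- sort(sample(genes$gene_id, min(fp$n_tumor_suppressors,
    nrow(genes))))
  feature_bundle(genes = genes, exons = as_tibble(exons),
    enhancers = enh, tumor_suppressors = tsg)
}

#' Simulate paired expression tables and an EM read-assignment problem
#'
#' Per-feature log-normal baseline abundances with negative-binomial counts
#' per sample. Gene and TE-family counts follow the same distribution in both
#' tissues (a distribution-level null), while full-length intact-L1 loci get
#' a `tumor_l1_log10_fc` log10 fold-change in tumor samples, emulating
#' tumor-restricted L1 promoter activity. A read-to-candidate-locus table for
#' the intact-L1 loci is also generated: each read originates from a locus
#' drawn proportionally to its true abundance and becomes multi-mapped with
#' probability `multi_rate` (gaining one or two decoy candidate loci).
#'
#' @inheritParams simulate_calls
#' @return List with `counts` (tibble: `feature_id`, `class`, `patient_id`,
#'   `tissue`, `sample_id`, `count`), `read_assignments` (tibble: `read_id`,
#'   `locus_id`), `loci` (tibble: `locus_id`, `family`, `intact`) and
#'   `true_l1_abundance`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "te_cohort_config"))
  cfg <- config
  ep <- cfg$expression
  set.seed(child_seed(cfg$seed, 30))
  pats <- patient_ids(cfg$n_patients)
  samples <- tidyr::expand_grid(patient_id = pats, tissue = cfg$tissues)

  base_tbl <- dplyr::bind_rows(
    tibble(feature_id = sprintf("GENE%05d", seq_len(ep$n_genes)),
      class = "gene",
      mu = stats::rlnorm(ep$n_genes, ep$gene_meanlog, ep$gene_sdlog)),
    tibble(feature_id = paste0("TE:", cfg$families),
      class = "te_family",
      mu = stats::rlnorm(length(cfg$families),
        ep$te_family_meanlog, ep$te_family_sdlog)),
    tibble(feature_id = sprintf("L1FLI%03d", seq_len(ep$n_intact_l1)),
      class = "intact_l1",
      mu = stats::rlnorm(ep$n_intact_l1, ep$l1_meanlog, ep$l1_sdlog))
  )

  counts <- tidyr::expand_grid(base_tbl, samples)
  counts$mu <- ifelse(counts$class == "intact_l1" & counts$tissue == "tumor",
    counts$mu * 10^ep$tumor_l1_log10_fc, counts$mu)
  counts$count <- stats::rnbinom(nrow(counts), mu = counts$mu,
    size = ep$nb_size)
  counts <- counts |>
    dplyr::mutate(sample_id = paste(.data$patient_id, .data$tissue,
      sep = ".")) |>
    dplyr::select("feature_id", "class", "patient_id", "tissue",
      "sample_id", "count")

  # EM read-assignment problem over the intact-L1 loci
  set.seed(child_seed(cfg$seed, 31))
  l1 <- base_tbl[base_tbl$class == "intact_l1", ]
  theta <- l1$mu / sum(l1$mu)
  origin <- sample(l1$feature_id, ep$n_reads_em, replace = TRUE,
    prob = theta)
  n_decoy <- ifelse(stats::runif(ep$n_reads_em) < ep$multi_rate,
    sample(1:2, ep$n_reads_em, replace = TRUE), 0L)
  reads <- tibble(read_id = sprintf("r%06d", seq_len(ep$n_reads_em)),
    locus_id = origin)
  decoys <- reads[rep(seq_len(nrow(reads)), n_decoy), ]
  if (nrow(decoys)) {
    decoys$locus_id <- sample(l1$feature_id, nrow(decoys), replace = TRUE)
  }
  assignments <- dplyr::distinct(dplyr::bind_rows(reads, decoys)) |>
    dplyr::arrange(.data$read_id, .data$locus_id)

  list(
    counts = counts,
    read_assignments = assignments,
    loci = tibble(locus_id = l1$feature_id, family = "L1", intact = TRUE),
    true_l1_abundance = stats::setNames(theta, l1$feature_id)
  )
}

#' Simulate a complete synthetic TE cohort
#'
#' Runs [simulate_truth()], [simulate_calls()], [simulate_features()] and
#' [simulate_expression()] under a single fanned-out seed and bundles the
#' results. Identical `config` (including `seed`) yields identical output.
#'
#' @param config A [cohort_config()].
#' @return A `te_cohort` list: `truth`, `calls`, `panel`, `features`,
#'   `expression`, `read_assignments`, `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 2, seed = 42))
#' dplyr::count(cohort$calls, caller_id)
simulate_cohort <- function(config) {
  truth <- simulate_truth(config)
  calls <- simulate_calls(truth, config)
  features <- simulate_features(config)
  expr <- simulate_expression(config)
  structure(
    list(truth = truth, calls = calls, panel = truth$panel,
         features = features, expression = expr$counts,
         read_assignments = expr$read_assignments,
         em_loci = expr$loci, config = config),
    class = "te_cohort"
  )
}

#' Write and read truth evaluation tables
#'
#' Serialises the truth layer as two TSV files (`truth_loci.tsv`,
#' `truth_carriers.tsv`) so downstream precision/recall can be computed by
#' external tools; the pair round-trips losslessly.
#'
#' @param truth A `te_truth`.
#' @param dir Output directory (created if absent).
#' @return `write_truth_tables()` returns the file paths invisibly;
#'   `read_truth_tables()` returns a list with `loci` and `carriers` tibbles.
#' @export
write_truth_tables <- function(truth, dir) {
  stopifnot(inherits(truth, "te_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("truth_loci.tsv", "truth_carriers.tsv"))
  readr::write_tsv(truth$loci, paths[1])
  readr::write_tsv(truth$carriers, paths[2])
  invisible(paths)
}

#' @rdname write_truth_tables
#' @export
read_truth_tables <- function(dir) {
  loci <- readr::read_tsv(file.path(dir, "truth_loci.tsv"),
    col_types = readr::cols(
      locus_id = "c", chrom = "c", pos = "i", family = "c", origin = "c",
      panel_af = "d", patient_id = "c", tissue = "c"))
  carriers <- readr::read_tsv(file.path(dir, "truth_carriers.tsv"),
    col_types = readr::cols(.default = "c"))
  list(loci = loci, carriers = carriers)
}
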