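#' Configure a synthetic matched normal/tumor TE cohort
#'
#' Builds the full parameter set for [simulate_cohort()]. The defaults describe
#' a nine-patient cohort of matched normal and primary-tumor samples whose
#' truth-level structure mirrors the regime reported for whole-genome TE
#' insertion surveys of matched cancer tissue: roughly 330 germline insertion
#' loci carried per patient (shared between the two tissues and partially
#' shared across patients, with panel-consistent allele frequencies), about 77
#' tissue-private somatic insertions per patient, a two-fold tumor excess of
#' somatic L1 insertions, ~35X sequencing depth, and bimodal supporting-read
#' counts in the emulated caller output.
#'
#' @param n_patients Number of patients; each contributes one normal and one
#'   tumor sample.
#' @param genome Data frame with columns `chrom` and `length` (bp) describing
#'   the chromosomes insertions are placed on.
#' @param families Character vector of active TE families.
#' @param family_weights Named numeric vector of sampling weights per family
#'   (normalised internally). Defaults approximate the Alu-dominated family
#'   mix of human TE call sets.
#' @param n_germline_loci Number of polymorphic germline insertion loci in the
#'   population. Each patient carries a locus with probability
#'   `1 - (1 - af)^2` (diploid Hardy-Weinberg carrier probability).
#' @param germline_af_shape1,germline_af_shape2 Shape parameters of the Beta
#'   distribution population allele frequencies are drawn from.
#' @param n_panel_extra Number of additional panel loci carried by no patient
#'   in the cohort (the panel emulates a large external reference population,
#'   which catalogues many insertions absent from any given small cohort).
#' @param somatic_rate_normal,somatic_rate_tumor Expected number of somatic
#'   insertions per sample per family (Poisson rates).
#' @param tumor_l1_multiplier Multiplier (>= 1) applied to the somatic L1 rate
#'   in tumor samples only; `2` encodes a two-fold tumor L1 excess.
#' @param caller_jitter_sd Standard deviation (bp) of the rounded-Gaussian
#'   positional error of reported calls around the true insertion point,
#'   truncated at +/- 100 bp so true calls stay within the merge window.
#' @param caller_fn_rate Per-caller probability of missing a true insertion.
#' @param caller_fp_rate Expected number of spurious calls per true call, per
#'   caller per sample (false positives are placed >= 500 bp from any truth
#'   locus).
#' @param support_real_size,support_noise_mean,support_noise_size Parameters of
#'   the two-component supporting-read mixture: genuine calls draw from a
#'   negative binomial with mean `mean_depth` and size `support_real_size`;
#'   false-positive calls draw from a low-mean negative binomial
#'   (`support_noise_mean`, `support_noise_size`). Together these produce the
#'   bimodal read-support distributions the 5-read filter exploits.
#' @param mean_depth Average sequencing depth of each sample (X).
#' @param min_locus_spacing Minimum distance (bp) between distinct simulated
#'   loci; kept well above the merge window so nearby truth loci cannot fuse.
#' @param expression List of expression-model parameters: `n_genes`,
#'   `n_intact_l1` (full-length intact L1 loci, default 145),
#'   `gene_meanlog`/`gene_sdlog` and `l1_meanlog`/`l1_sdlog` (log-normal
#'   baseline abundances), `te_family_meanlog`/`te_family_sdlog`, `nb_size`
#'   (negative-binomial dispersion of counts around the baseline),
#'   `tumor_l1_log10_fc` (log10 fold-change applied to intact-L1 loci in tumor
#'   samples), `n_reads_em` and `multi_rate` (size and multi-mapping rate of
#'   the read-to-locus assignment table for the EM quantifier).
#' @param features List of feature-model parameters: `n_genes` gene models
#'   (with `exons_per_gene` range and `gene_span` bp), `n_enhancers` enhancer
#'   intervals of `enhancer_width` bp, and `n_tumor_suppressors` gene ids
#'   sampled into the tumor-suppressor list.
#' @param seed Integer seed. A single seed fans out deterministically to
#'   per-stream child seeds (loci, carriers, callers, features, expression) so
#'   sub-streams are independently reproducible.
#'
#' @return An object of class `te_cohort_config` (a validated list).
#' @seealso [simulate_cohort()], [read_cohort_config()]
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 3, seed = 7)
#' cfg$somatic_rate_tumor
cohort_config <- function(n_patients = 9,
                          genome = tibble::tibble(
                            chrom = paste0("chr", 1:4),
                            length = rep(30e6, 4)
                          ),
                          families = c("Alu", "L1", "SVA"),
                          family_weights = c(Alu = 0.85, L1 = 0.12, SVA = 0.03),
                          n_germline_loci = 850,
                          germline_af_shape1 = 0.7,
                          germline_af_shape2 = 2,
                          n_panel_extra = 150,
                          somatic_rate_normal = 11,
                          somatic_rate_tumor = 11,
                          tumor_l1_multiplier = 2,
                          caller_jitter_sd = 15,
                          caller_fn_rate = 0.02,
                          caller_fp_rate = 0.05,
                          support_real_size = 12,
                          support_noise_mean = 2,
                          support_noise_size = 2,
                          mean_depth = 35,
                          min_locus_spacing = 500,
                          expression = list(),
                          features = list(),
                          seed = 1L) {
  expr_defaults <- list(
    n_genes = 2000, n_intact_l1 = 145,
    gene_meanlog = log(500), gene_sdlog = 1,
    te_family_meanlog = log(5e4), te_family_sdlog = 0.5,
    l1_meanlog = log(50), l1_sdlog = 0.8,
    nb_size = 20, tumor_l1_log10_fc = 1,
    n_reads_em = 5000, multi_rate = 0.3
  )
  feat_defaults <- list(
    n_genes = 300, exons_per_gene = c(2L, 8L), gene_span = 100000,
    n_enhancers = 150, enhancer_width = 1000,
    n_tumor_suppressors = 30
  )
  cfg <- list(
    n_patients = as.integer(n_patients),
    tissues = c("normal", "tumor"),
    genome = tibble::as_tibble(genome),
    families = as.character(families),
    family_weights = family_weights,
    n_germline_loci = as.integer(n_germline_loci),
    germline_af_shape1 = germline_af_shape1,
    germline_af_shape2 = germline_af_shape2,
    n_panel_extra = as.integer(n_panel_extra),
    somatic_rate_normal = somatic_rate_normal,
    somatic_rate_tumor = somatic_rate_tumor,
    tumor_l1_multiplier = tumor_l1_multiplier,
    caller_jitter_sd = caller_jitter_sd,
    caller_fn_rate = caller_fn_rate,
    caller_fp_rate = caller_fp_rate,
    support_real_size = support_real_size,
    support_noise_mean = support_noise_mean,
    support_noise_size = support_noise_size,
    mean_depth = mean_depth,
    min_locus_spacing = min_locus_spacing,
    expression = utils::modifyList(expr_defaults, expression),
    features = utils::modifyList(feat_defaults, features),
    seed = as.integer(seed)
  )
  class(cfg) <- "te_cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_patients < 1) {
    abort("`n_patients` must be >= 1.", class = "te_config_error")
  }
  if (!all(c("chrom", "length") %in% names(cfg$genome)) ||
      nrow(cfg$genome) == 0L) {
    abort("`genome` needs columns `chrom` and `length` and >= 1 row.",
      class = "te_config_error")
  }
  if (any(cfg$genome$length <= 0)) {
    abort("chromosome lengths must be positive.", class = "te_config_error")
  }
  if (length(cfg$families) == 0L) {
    abort("`families` must be non-empty.", class = "te_config_error")
  }
  if (!all(cfg$families %in% names(cfg$family_weights))) {
    abort("every family needs a weight in `family_weights`.",
      class = "te_config_error")
  }
  probs <- c(cfg$caller_fn_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("`caller_fn_rate` must lie in [0, 1].", class = "te_config_error")
  }
  rates <- c(cfg$somatic_rate_normal, cfg$somatic_rate_tumor,
             cfg$caller_fp_rate)
  if (any(rates < 0)) {
    abort("rates must be non-negative.", class = "te_config_error")
  }
  if (cfg$tumor_l1_multiplier < 1) {
    abort("`tumor_l1_multiplier` must be >= 1.", class = "te_config_error")
  }
  if (cfg$germline_af_shape1 <= 0 || cfg$germline_af_shape2 <= 0) {
    abort("Beta shape parameters must be positive.", class = "te_config_error")
  }
  if (cfg$mean_depth <= 0) {
    abort("`mean_depth` must be positive.", class = "te_config_error")
  }
  cfg
}

#' Read or write a cohort configuration as YAML
#'
#' Round-trips the scalar and vector fields of a [cohort_config()] through a
#' flat YAML file; the genome table is stored as parallel `chrom`/`length`
#' sequences.
#'
#' @param path File path.
#' @param config A `te_cohort_config`.
#' @return `read_cohort_config()` returns a `te_cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$genome <- tibble::tibble(
    chrom = as.character(raw$genome$chrom),
    length = as.numeric(raw$genome$length)
  )
  raw$family_weights <- unlist(raw$family_weights)
  do.call(cohort_config, raw)
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "te_cohort_config"))
  out <- unclass(config)
  out$genome <- list(chrom = out$genome$chrom, length = out$genome$length)
  out$family_weights <- as.list(out$family_weights)
  out$tissues <- NULL  # fixed pair, not configurable
  yaml::write_yaml(out, path)
  invisible(path)
}

# Deterministic fan-out of the global seed into per-stream child seeds.
# Values stay below 2^31 - 1 so set.seed() always accepts them.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 7919) %% 2147483629
}
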