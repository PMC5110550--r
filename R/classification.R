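# Shared vs tissue-specific partitioning and cohort-private insertions.

#' Partition one patient's insertions into shared and tissue-specific sets
#'
#' Matches a patient's normal-tissue consensus insertions against the tumor
#' set using the same greedy nearest one-to-one assignment (same family,
#' positions within `window_bp`) used for caller merging. Matched pairs are
#' `shared` (presumed germline); unmatched insertions are `normal_only` or
#' `tumor_only` tissue-specific candidates.
#'
#' @param normal,tumor Consensus insertion tibbles for one patient's two
#'   tissues (columns as returned by [merge_two_callers()]; `sample_id` must
#'   identify a single patient).
#' @param window_bp Matching window in bp (default 100).
#' @param patient_id Patient identifier; inferred from `sample_id` (the part
#'   before the last `.`) when missing.
#' @return A `te_patient_profile` tibble: `patient_id`, `status`
#'   (`shared`/`normal_only`/`tumor_only`), `chrom`, `pos` (representative
#'   position: rounded mean for shared pairs), `family`, `pos_normal`,
#'   `pos_tumor`, `support_normal`, `support_tumor`. The three status classes
#'   partition the patient's matched loci: each locus appears exactly once.
#' @export
pair_tissues <- function(normal, tumor, window_bp = 100, patient_id = NULL) {
  infer_patient <- function(calls) {
    if (nrow(calls) == 0L) return(character())
    unique(sub("\\.[^.]*$", "", calls$sample_id))
  }
  pats <- unique(c(infer_patient(normal), infer_patient(tumor)))
  if (length(pats) > 1L) {
    abort(paste0("inputs mix patients: ", paste(pats, collapse = ", ")),
      class = "te_input_error")
  }
  patient_id <- patient_id %||% (if (length(pats)) pats else NA_character_)

  m <- greedy_match(normal, tumor, window_bp)
  ns <- normal[m$idx_a, ]
  ts <- tumor[m$idx_b, ]
  shared <- tibble(
    patient_id = patient_id, status = "shared",
    chrom = ns$chrom,
    pos = as.integer(round_half_up((ns$pos + ts$pos) / 2)),
    family = ns$family,
    pos_normal = ns$pos, pos_tumor = ts$pos,
    support_normal = ns$support_reads, support_tumor = ts$support_reads
  )
  n_only <- normal[setdiff(seq_len(nrow(normal)), m$idx_a), ]
  t_only <- tumor[setdiff(seq_len(nrow(tumor)), m$idx_b), ]
  out <- dplyr::bind_rows(
    shared,
    tibble(patient_id = patient_id, status = "normal_only",
      chrom = n_only$chrom, pos = n_only$pos, family = n_only$family,
      pos_normal = n_only$pos, pos_tumor = NA_integer_,
      support_normal = n_only$support_reads, support_tumor = NA_integer_),
    tibble(patient_id = patient_id, status = "tumor_only",
      chrom = t_only$chrom, pos = t_only$pos, family = t_only$family,
      pos_normal = NA_integer_, pos_tumor = t_only$pos,
      support_normal = NA_integer_, support_tumor = t_only$support_reads)
  ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  class(out) <- c("te_patient_profile", class(out))
  out
}

#' Construct a cohort summary from known counts
#'
#' Low-level constructor used when the per-locus detail is unavailable and
#' only the headline counts are known (e.g. when re-deriving summary
#' statistics from a published table). [find_private_insertions()] builds the
#' same object from patient profiles.
#'
#' @param total_insertions Total consensus loci summed over patients, with a
#'   shared locus counted once per patient (not once per tissue).
#' @param unique_insertions Number of private insertions: tissue-specific
#'   loci found in only one patient and one tissue.
#' @param unique_normal,unique_tumor Optional split of `unique_insertions` by
#'   tissue.
#' @param n_patients Number of patients summarised.
#' @param counts Optional tibble of per-family, per-tissue unique counts.
#' @param private Optional tibble of the private insertions themselves.
#' @return A `te_cohort_summary` object.
#' @export
cohort_summary <- function(total_insertions, unique_insertions,
                           unique_normal = NA_integer_,
                           unique_tumor = NA_integer_,
                           n_patients = NA_integer_,
                           counts = NULL, private = NULL) {
  if (unique_insertions > total_insertions) {
    abort("`unique_insertions` cannot exceed `total_insertions`.",
      class = "te_input_error")
  }
  structure(
    list(total_insertions = total_insertions,
         unique_insertions = unique_insertions,
         unique_normal = unique_normal, unique_tumor = unique_tumor,
         n_patients = n_patients, counts = counts, private = private,
         locus_convention = "shared loci counted once per patient"),
    class = "te_cohort_summary"
  )
}

#' Identify cohort-private insertions and summarise the cohort
#'
#' A tissue-specific insertion (status `normal_only` or `tumor_only`) is
#' *private* if no insertion of the same family lies within `window_bp` of it
#' in any other patient (either tissue) nor in the same patient's other
#' tissue. Shared insertions are presumed germline and are never private, but
#' they do disqualify nearby tissue-specific calls in other patients
#' (cross-patient recurrence).
#'
#' @param profiles One or more patient profiles from [pair_tissues()],
#'   row-bound into a single tibble.
#' @param window_bp Recurrence window in bp (default 100, the same
#'   co-location window used for caller merging).
#' @return A `te_cohort_summary`; see [cohort_summary()]. `total_insertions`
#'   counts each profile row once (shared loci once per patient), `private`
#'   holds the private rows, and `counts` breaks unique insertions down by
#'   family and tissue.
#' @export
find_private_insertions <- function(profiles, window_bp = 100) {
  stopifnot(nrow(profiles) >= 1L)
  prof <- dplyr::mutate(profiles, .row = dplyr::row_number())

  # occurrences: one row per (patient, tissue) appearance of a locus
  occ <- dplyr::bind_rows(
    prof |> dplyr::filter(!is.na(.data$pos_normal)) |>
      dplyr::transmute(.data$chrom, .data$family, .data$patient_id,
        tissue = "normal", opos = .data$pos_normal),
    prof |> dplyr::filter(!is.na(.data$pos_tumor)) |>
      dplyr::transmute(.data$chrom, .data$family, .data$patient_id,
        tissue = "tumor", opos = .data$pos_tumor)
  )

  specific <- prof |>
    dplyr::filter(.data$status != "shared") |>
    dplyr::mutate(tissue = ifelse(.data$status == "normal_only",
      "normal", "tumor"))
  hits <- dplyr::inner_join(
    specific[, c(".row", "chrom", "family", "patient_id", "tissue", "pos")],
    occ, by = c("chrom", "family"), suffix = c("", "_occ"),
    relationship = "many-to-many"
  ) |>
    dplyr::filter(
      abs(.data$pos - .data$opos) <= window_bp,
      .data$patient_id != .data$patient_id_occ |
        .data$tissue != .data$tissue_occ
    )
  private <- specific[!specific$.row %in% hits$.row, ] |>
    dplyr::select(-".row")

  counts <- private |>
    dplyr::count(.data$family, .data$tissue, name = "n_unique")
  summary <- cohort_summary(
    total_insertions = nrow(prof),
    unique_insertions = nrow(private),
    unique_normal = sum(private$tissue == "normal"),
    unique_tumor = sum(private$tissue == "tumor"),
    n_patients = dplyr::n_distinct(prof$patient_id),
    counts = counts, private = private
  )
  summary
}

#' Average number of private insertions per patient
#'
#' @param summary A `te_cohort_summary`.
#' @param n_patients Number of patients (defaults to the summary's own
#'   count); must be >= 1.
#' @return `unique_insertions / n_patients`, rounded half-up to the nearest
#'   integer.
#' @export
#' @examples
#' average_private_per_patient(cohort_summary(3672, 693), n_patients = 9)
average_private_per_patient <- function(summary,
                                        n_patients = summary$n_patients) {
  stopifnot(inherits(summary, "te_cohort_summary"))
  if (is.na(n_patients) || n_patients < 1) {
    abort("`n_patients` must be >= 1.", class = "te_parameter_error")
  }
  round_half_up(summary$unique_insertions / n_patients)
}

#' Percentage of insertions shared between tissues
#'
#' @param summary A `te_cohort_summary` with `total_insertions` > 0.
#' @return `100 * (total - unique) / total`, rounded to one decimal.
#' @export
#' @examples
#' shared_fraction(cohort_summary(3672, 693))
shared_fraction <- function(summary) {
  stopifnot(inherits(summary, "te_cohort_summary"))
  if (summary$total_insertions <= 0) {
    abort("`total_insertions` must be positive.",
      class = "te_parameter_error")
  }
  round(100 * (summary$total_insertions - summary$unique_insertions) /
    summary$total_insertions, 1)
}

#' Tumor-vs-normal excess of unique insertions
#'
#' Ratio of tumor-specific to normal-specific private insertion counts.
#'
#' @param summary A `te_cohort_summary` with the tissue split populated.
#' @return `unique_tumor / unique_normal`.
#' @export
tissue_excess_ratio <- function(summary) {
  stopifnot(inherits(summary, "te_cohort_summary"))
  if (is.na(summary$unique_normal) || is.na(summary$unique_tumor)) {
    abort("summary lacks the per-tissue unique split.",
      class = "te_parameter_error")
  }
  if (summary$unique_normal == 0) {
    abort("no normal-specific insertions; ratio undefined.",
      class = "te_parameter_error")
  }
  summary$unique_tumor / summary$unique_normal
}

#' Score somatic (private) detection against a simulated truth set
#'
#' Matches the private insertions of a cohort summary against the somatic
#' truth records of a synthetic cohort (same patient, tissue and family,
#' positions within `window_bp`) and reports precision and recall.
#'
#' @param summary A `te_cohort_summary` from [find_private_insertions()].
#' @param truth A `te_truth` from [simulate_truth()].
#' @param window_bp Matching window in bp.
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
score_somatic_detection <- function(summary, truth, window_bp = 100) {
  stopifnot(inherits(summary, "te_cohort_summary"),
    inherits(truth, "te_truth"))
  private <- summary$private
  som <- truth$loci[truth$loci$origin == "somatic", ]
  if (nrow(private) == 0L) {
    return(tibble(tp = 0L, fp = 0L, fn = nrow(som),
      precision = NA_real_, recall = if (nrow(som)) 0 else NA_real_))
  }
  m <- dplyr::inner_join(
    dplyr::mutate(private, .p = dplyr::row_number()),
    dplyr::mutate(som, .t = dplyr::row_number()),
    by = c("chrom", "family", "patient_id", "tissue"),
    suffix = c("", "_truth"), relationship = "many-to-many"
  ) |>
    dplyr::filter(abs(.data$pos - .data$pos_truth) <= window_bp)
  tp <- dplyr::n_distinct(m$.p)
  matched_truth <- dplyr::n_distinct(m$.t)
  tibble(
    tp = tp,
    fp = nrow(private) - tp,
    fn = nrow(som) - matched_truth,
    precision = tp / nrow(private),
    recall = if (nrow(som)) matched_truth / nrow(som) else NA_real_
  )
}

#' Run the full insertion pipeline on a synthetic cohort
#'
#' Convenience wrapper: merges the two callers per sample, applies the
#' read-support filter, pairs tissues per patient, finds cohort-private
#' insertions and scores them against the simulated truth.
#'
#' @param cohort A `te_cohort` from [simulate_cohort()].
#' @param window_bp Co-location window in bp.
#' @param min_reads,depth_multiplier Support-filter parameters; see
#'   [filter_by_support()].
#' @return List with `consensus` (filtered consensus calls, all samples),
#'   `profiles` (row-bound patient profiles), `summary`
#'   (`te_cohort_summary`) and `score` (precision/recall tibble).
#' @export
analyze_cohort <- function(cohort, window_bp = 100, min_reads = 5,
                           depth_multiplier = 4) {
  stopifnot(inherits(cohort, "te_cohort"))
  callers <- sort(unique(cohort$calls$caller_id))
  stopifnot(length(callers) == 2L)
  consensus <- cohort$calls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_map(function(df, key) {
      merged <- merge_two_callers(
        df[df$caller_id == callers[1], ],
        df[df$caller_id == callers[2], ],
        window_bp = window_bp
      )
      filter_by_support(merged, min_reads = min_reads,
        depth_multiplier = depth_multiplier,
        mean_depth = cohort$config$mean_depth)
    }, .keep = TRUE) |>
    dplyr::bind_rows()
  consensus$patient_id <- sub("\\.[^.]*$", "", consensus$sample_id)

  profiles <- consensus |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_map(function(df, key) {
      pair_tissues(df[df$tissue == "normal", ], df[df$tissue == "tumor", ],
        window_bp = window_bp, patient_id = key$patient_id)
    }, .keep = TRUE) |>
    dplyr::bind_rows()

  summary <- find_private_insertions(profiles, window_bp = window_bp)
  list(consensus = consensus, profiles = profiles, summary = summary,
    score = score_somatic_detection(summary, cohort$truth, window_bp))
}
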