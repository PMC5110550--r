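# Two-caller consensus merging and read-support filtering.

# Greedy nearest-distance one-to-one matching between two call tables.
# Candidate pairs are same-chromosome, same-family pairs within `window_bp`;
# they are consumed in order of (distance, lower position of the pair, then
# the remaining coordinates) so the result is deterministic. Returns the
# matched row indices and their distance.
greedy_match <- function(a, b, window_bp) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble(idx_a = integer(), idx_b = integer(), dist = integer()))
  }
  pairs <- dplyr::inner_join(
    dplyr::mutate(a[, c("chrom", "pos", "family")], idx_a = dplyr::row_number()),
    dplyr::mutate(b[, c("chrom", "pos", "family")], idx_b = dplyr::row_number()),
    by = c("chrom", "family"), suffix = c("_a", "_b"),
    relationship = "many-to-many"
  ) |>
    dplyr::mutate(dist = abs(.data$pos_a - .data$pos_b)) |>
    dplyr::filter(.data$dist <= window_bp) |>
    dplyr::arrange(.data$dist, pmin(.data$pos_a, .data$pos_b),
      .data$pos_a, .data$pos_b, .data$idx_a, .data$idx_b)
  if (nrow(pairs) == 0L) {
    return(tibble(idx_a = integer(), idx_b = integer(), dist = integer()))
  }
  used_a <- logical(nrow(a))
  used_b <- logical(nrow(b))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ia <- pairs$idx_a[i]
    ib <- pairs$idx_b[i]
    if (!used_a[ia] && !used_b[ib]) {
      used_a[ia] <- TRUE
      used_b[ib] <- TRUE
      keep[i] <- TRUE
    }
  }
  pairs[keep, c("idx_a", "idx_b", "dist")]
}

round_half_up <- function(x) floor(x + 0.5)

check_single_sample <- function(calls, arg) {
  if (nrow(calls) == 0L) return(invisible(NULL))
  ids <- unique(calls$sample_id)
  if (length(ids) > 1L) {
    abort(paste0("`", arg, "` mixes sample_ids: ",
      paste(ids, collapse = ", ")), class = "te_input_error")
  }
  invisible(NULL)
}

#' Merge two callers' insertion calls into consensus insertions
#'
#' Calls from two independent TE insertion callers on the same sample are
#' intersected: predictions of the same family on the same chromosome whose
#' positions lie within `window_bp` of each other (inclusive) are considered
#' the same insertion. Matching is a deterministic greedy one-to-one
#' assignment over candidate pairs sorted by distance (ties broken by lower
#' position), so each call contributes to at most one consensus. The
#' consensus position is the arithmetic mean of the matched pair, rounded
#' half-up; consensus read support is the maximum of the two calls' supports
#' (the filter downstream asks whether sufficient evidence exists, not for an
#' average).
#'
#' @param calls_a,calls_b Call tables from one caller each, single sample:
#'   tibbles with at least `chrom`, `pos` (1-based), `family`,
#'   `support_reads`, `caller_id`, `sample_id`, `tissue`.
#' @param window_bp Maximum distance (bp) for two predictions to be merged;
#'   the conventional value is 100 (a +/- 100 bp co-location window).
#' @return Tibble of consensus insertions sorted by (`chrom`, `pos`):
#'   `chrom`, `pos`, `family`, `support_reads`, `sample_id`, `tissue`, plus
#'   the contributing calls' `pos_a`, `pos_b`, `support_a`, `support_b`,
#'   `caller_a`, `caller_b`.
#' @export
#' @examples
#' a <- tibble::tibble(chrom = "chr1", pos = 1000L, family = "L1",
#'   support_reads = 12L, caller_id = "a", sample_id = "s1", tissue = "tumor")
#' b <- dplyr::mutate(a, pos = 1050L, caller_id = "b", support_reads = 9L)
#' merge_two_callers(a, b)
merge_two_callers <- function(calls_a, calls_b, window_bp = 100) {
  stopifnot(window_bp >= 0)
  check_single_sample(calls_a, "calls_a")
  check_single_sample(calls_b, "calls_b")
  if (nrow(calls_a) && nrow(calls_b) &&
      !identical(unique(calls_a$sample_id), unique(calls_b$sample_id))) {
    abort("`calls_a` and `calls_b` come from different samples.",
      class = "te_input_error")
  }
  m <- greedy_match(calls_a, calls_b, window_bp)
  a <- calls_a[m$idx_a, ]
  b <- calls_b[m$idx_b, ]
  tibble(
    chrom = a$chrom,
    pos = as.integer(round_half_up((a$pos + b$pos) / 2)),
    family = a$family,
    support_reads = pmax(a$support_reads, b$support_reads),
    sample_id = a$sample_id,
    tissue = a$tissue,
    pos_a = a$pos, pos_b = b$pos,
    support_a = a$support_reads, support_b = b$support_reads,
    caller_a = a$caller_id, caller_b = b$caller_id
  ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Filter consensus insertions by supporting-read count
#'
#' Retains insertions whose read support lies in the closed interval
#' `[min_reads, depth_multiplier * mean_depth]`. The lower bound removes the
#' low-support noise mode of the typically bimodal support distribution; the
#' upper bound removes calls in regions with anomalously high coverage, which
#' are enriched for ambiguously mapped reads. Input order is preserved.
#'
#' @param calls Tibble with a `support_reads` column (typically consensus
#'   insertions from [merge_two_callers()]).
#' @param min_reads Minimum supporting reads (default 5).
#' @param depth_multiplier Upper cut-off as a multiple of the sample's mean
#'   depth (default 4).
#' @param mean_depth Average sequencing depth of the sample (must be > 0).
#' @return The retained rows of `calls`.
#' @export
filter_by_support <- function(calls, min_reads = 5, depth_multiplier = 4,
                              mean_depth) {
  if (mean_depth <= 0) {
    abort("`mean_depth` must be positive.", class = "te_parameter_error")
  }
  upper <- depth_multiplier * mean_depth
  calls[calls$support_reads >= min_reads & calls$support_reads <= upper, ]
}

#' Histogram of supporting-read counts
#'
#' Bins `support_reads` into fixed-width bins; useful for inspecting the
#' bimodality that motivates the 5-read lower cut-off.
#'
#' @param calls Tibble with a `support_reads` column.
#' @param bin_width Bin width in reads (>= 1).
#' @return A `te_support_histogram` tibble: `bin_start`, `bin_end`
#'   (half-open `[bin_start, bin_end)`), `n`. Counts sum to `nrow(calls)`.
#' @export
support_histogram <- function(calls, bin_width = 1L) {
  stopifnot(bin_width >= 1)
  if (nrow(calls) == 0L) {
    out <- tibble(bin_start = integer(), bin_end = integer(), n = integer())
  } else {
    out <- tibble(bin_start = floor(calls$support_reads / bin_width) *
        bin_width) |>
      dplyr::count(.data$bin_start) |>
      dplyr::mutate(bin_end = .data$bin_start + bin_width,
        .after = "bin_start")
  }
  class(out) <- c("te_support_histogram", class(out))
  out
}
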