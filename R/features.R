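# Genomic-context classification and tumor-suppressor driver screening.

#' Bundle gene models, enhancers and a tumor-suppressor list
#'
#' Validates and packages the genome features used by [classify_contexts()]
#' and [flag_candidate_drivers()]. All intervals are 0-based half-open.
#'
#' @param genes Tibble: `gene_id`, `chrom`, `strand` (`+`/`-`), `tx_start`,
#'   `tx_end` (transcript span).
#' @param exons Tibble: `gene_id`, `chrom`, `start`, `end`; every exon must
#'   nest within its gene's transcript span.
#' @param enhancers Tibble: `chrom`, `start`, `end`.
#' @param tumor_suppressors Character vector of gene ids (a curated
#'   cancer-gene list).
#' @return A `te_feature_bundle` list.
#' @export
feature_bundle <- function(genes, exons, enhancers, tumor_suppressors) {
  genes <- as_tibble(genes)
  exons <- as_tibble(exons)
  enhancers <- as_tibble(enhancers)
  if (any(genes$tx_start >= genes$tx_end) ||
      (nrow(exons) && any(exons$start >= exons$end)) ||
      (nrow(enhancers) && any(enhancers$start >= enhancers$end))) {
    abort("intervals must satisfy start < end.",
      class = "te_validation_error")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'.", class = "te_validation_error")
  }
  if (nrow(exons)) {
    span <- genes[match(exons$gene_id, genes$gene_id), ]
    if (any(is.na(span$gene_id)) ||
        any(exons$start < span$tx_start | exons$end > span$tx_end |
            exons$chrom != span$chrom)) {
      abort("every exon must nest within its gene's transcript span.",
        class = "te_validation_error")
    }
  }
  structure(
    list(genes = genes, exons = exons, enhancers = enhancers,
         tumor_suppressors = as.character(tumor_suppressors)),
    class = "te_feature_bundle"
  )
}

# Overlap of 1-based insertion points with 0-based half-open intervals,
# via GenomicRanges. Returns for each insertion the index of the first
# overlapping interval (ordered by a deterministic key), or NA.
point_overlap <- function(insertions, intervals, order_key) {
  if (nrow(intervals) == 0L || nrow(insertions) == 0L) {
    return(rep(NA_integer_, nrow(insertions)))
  }
  ord <- order(order_key)
  iv <- intervals[ord, ]
  q <- GenomicRanges::GRanges(insertions$chrom,
    IRanges::IRanges(insertions$pos, width = 1L))
  s <- GenomicRanges::GRanges(iv$chrom,
    IRanges::IRanges(iv$start + 1L, iv$end))
  hits <- GenomicRanges::findOverlaps(q, s, select = "first")
  ord[hits]
}

#' Classify the genomic context of insertions
#'
#' Assigns each insertion exactly one context label with precedence
#' `exonic > regulatory (enhancer) > intronic > intergenic`. The insertion's
#' 1-based point is converted to 0-based before the half-open interval test.
#' Where several features of the same kind contain a point, the one with the
#' lexically smallest gene id (or leftmost enhancer) is reported, so the
#' labelling is deterministic.
#'
#' @param insertions Tibble with `chrom` and `pos` (1-based) columns.
#' @param features A [feature_bundle()].
#' @return `insertions` plus `context` (factor exonic/regulatory/intronic/
#'   intergenic), `gene_id` (containing gene for exonic/intronic, else `NA`)
#'   and `enhancer_id` (row index into `features$enhancers`, regulatory
#'   only).
#' @export
classify_contexts <- function(insertions, features) {
  stopifnot(inherits(features, "te_feature_bundle"))
  ins <- as_tibble(insertions)
  n <- nrow(ins)

  ex_hit <- point_overlap(ins, features$exons, features$exons$gene_id)
  enh <- features$enhancers
  enh_hit <- point_overlap(ins, enh,
    order(order(enh$chrom, enh$start)))
  tx <- features$genes |>
    dplyr::transmute(.data$gene_id, .data$chrom,
      start = .data$tx_start, end = .data$tx_end)
  tx_hit <- point_overlap(ins, tx, tx$gene_id)

  context <- dplyr::case_when(
    !is.na(ex_hit) ~ "exonic",
    !is.na(enh_hit) ~ "regulatory",
    !is.na(tx_hit) ~ "intronic",
    .default = "intergenic"
  )
  out <- ins
  out$context <- factor(context,
    levels = c("exonic", "regulatory", "intronic", "intergenic"))
  out$gene_id <- dplyr::case_when(
    context == "exonic" ~ features$exons$gene_id[ex_hit],
    context == "intronic" ~ tx$gene_id[tx_hit],
    .default = NA_character_
  )
  out$enhancer_id <- ifelse(context == "regulatory", enh_hit, NA_integer_)
  out
}

#' Summarise genomic-context counts
#'
#' Counts and percentages per context class. The classes are mutually
#' exclusive under the classification precedence, so counts partition the
#' input. Note that published breakdowns of this kind sometimes label the
#' non-genic class "intragenic" even though the surrounding arithmetic
#' implies intergenic; here the class is always the non-exonic,
#' non-regulatory, non-intronic remainder.
#'
#' @param labels Output of [classify_contexts()] (or any tibble with a
#'   `context` column).
#' @return Tibble `context`, `n`, `pct` (percent of total, one decimal);
#'   empty input gives an empty table.
#' @export
#' @examples
#' labels <- tibble::tibble(context = rep(c("intergenic", "intronic",
#'   "exonic"), c(141, 246, 6)))
#' summarize_contexts(labels)
summarize_contexts <- function(labels) {
  if (nrow(labels) == 0L) {
    return(tibble(context = character(), n = integer(), pct = numeric()))
  }
  lev <- c("exonic", "regulatory", "intronic", "intergenic")
  tibble(context = factor(labels$context, levels = lev)) |>
    dplyr::count(.data$context, .drop = FALSE) |>
    dplyr::mutate(pct = round(100 * .data$n / nrow(labels), 1))
}

# nearest TSS (strand-aware transcription start) within `cap` bp of a point;
# cap <= 0 disables linkage entirely.
nearest_tss_gene <- function(chrom, pos, genes, cap) {
  if (cap <= 0 || nrow(genes) == 0L) return(NA_character_)
  tss <- ifelse(genes$strand == "+", genes$tx_start + 1L, genes$tx_end)
  d <- ifelse(genes$chrom == chrom, abs(tss - pos), Inf)
  i <- which(d <= cap)
  if (length(i) == 0L) return(NA_character_)
  i <- i[order(d[i], genes$gene_id[i])][1]
  genes$gene_id[i]
}

#' Flag candidate driver insertions in tumor suppressors
#'
#' Screens tumor-private insertion labels for the pattern most likely to be
#' functionally relevant: an insertion in an exon of a tumor-suppressor
#' gene, or in an enhancer whose nearest transcription start site (within
#' `tss_cap` bp) belongs to a tumor suppressor. When per-gene expression
#' changes are supplied, candidates whose gene is down-regulated in tumor
#' are marked `concordant` — the signature of an insertion plausibly
#' silencing its tumor suppressor.
#'
#' @param labels Output of [classify_contexts()] computed on tumor-private
#'   insertions only (shared, presumed-germline insertions are out of
#'   scope).
#' @param features The [feature_bundle()] used for classification.
#' @param expression_delta Optional tibble `gene_id`, `delta` with the
#'   tumor-minus-normal expression change (log scale) per gene.
#' @param tss_cap Enhancer-to-gene linkage cap in bp (default 50000); with
#'   `tss_cap = 0` regulatory insertions never link to a gene.
#' @return Tibble of candidates ranked by ascending expression delta (most
#'   down-regulated first), with `linked_gene` and `concordance`
#'   (`concordant`/`discordant`/`NA`).
#' @export
flag_candidate_drivers <- function(labels, features,
                                   expression_delta = NULL,
                                   tss_cap = 50000) {
  stopifnot(inherits(features, "te_feature_bundle"))
  lab <- as_tibble(labels)
  lab$linked_gene <- lab$gene_id
  reg <- which(lab$context == "regulatory")
  for (i in reg) {
    lab$linked_gene[i] <- nearest_tss_gene(lab$chrom[i], lab$pos[i],
      features$genes, tss_cap)
  }
  cand <- lab[lab$context %in% c("exonic", "regulatory") &
                !is.na(lab$linked_gene) &
                lab$linked_gene %in% features$tumor_suppressors, ]
  if (!is.null(expression_delta)) {
    cand <- dplyr::left_join(cand,
      dplyr::rename(expression_delta[, c("gene_id", "delta")],
        linked_gene = "gene_id"),
      by = "linked_gene")
    cand$concordance <- ifelse(is.na(cand$delta), NA_character_,
      ifelse(cand$delta < 0, "concordant", "discordant"))
    cand <- dplyr::arrange(cand, .data$delta)
  }
  cand
}
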