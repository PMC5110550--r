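---
title: "Somatic TE insertion and expression analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic TE insertion and expression analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaTE)
library(dplyr)
```

`somaTE` analyses somatic transposable-element (TE) activity in matched
normal/tumor sample pairs: consensus insertion calling from two independent
callers, partitioning into germline-like and tissue-specific insertions,
population-frequency annotation, L1 enrichment statistics, genome-feature
driver screening, and expression comparison with an EM multi-mapper
quantifier. This vignette explains the models behind each step, the
parameters that matter, what the synthetic cohort generator does and does
not emulate, and the numerical choices made where conventions were open.

## The detection model

TE insertion callers based on discordant read-pair mapping localise an
insertion only approximately. Two design constants follow from that:

* **Co-location window (`window_bp = 100`)**. Two predictions within
  ±100 bp (inclusive: distance ≤ 100 merges) are treated as the same
  insertion — for merging the two callers, for pairing a patient's normal
  and tumor call sets, for cross-patient recurrence and for panel matching.
  A single window is used everywhere because all four comparisons face the
  same positional uncertainty. The approximation can collapse genuinely
  distinct nearby events into one; this is accepted and documented rather
  than resolved, since call sets provide no information below the window
  scale.
* **Support filter (`min_reads = 5`, `depth_multiplier = 4`)**. Supporting
  read counts of real and spurious calls form a bimodal mixture; calls
  below 5 reads are enriched for noise, and calls above 4× the sample's
  mean depth sit in regions of anomalous, ambiguously mapped coverage. The
  filter keeps the closed interval `[5, 4 × mean_depth]`.

**Matching is greedy nearest-distance, one-to-one.** When one caller's call
lies within the window of several calls from the other caller, candidate
pairs are consumed in order of (distance, lower position, remaining
coordinates), each call participating in at most one consensus. This is
deterministic and `O(n log n)`. It is *not* a maximum-cardinality matcher on
adversarial inputs: a chain of calls each ~90 bp apart can make the greedy
choice block a second pair. Under the positional model the package targets —
true loci separated by ≥ 500 bp and jitter bounded by the window — each
call has at most one plausible partner and greedy matching coincides with
the optimal assignment, which is what the oracle-equivalence tests verify.

The consensus position is the rounded (half-up) mean of the pair; consensus
support is the **maximum** of the two callers' supports, because the filter
asks whether sufficient evidence exists, not for an average of two
different counting conventions. The support filter is applied to consensus
calls (after intersection); filtering per-caller first would only be
stricter and can be emulated by pre-filtering the inputs.

## Somatic classification and private insertions

Insertions present in both tissues of a patient are presumed germline;
tissue-specific insertions are somatic candidates. A tissue-specific
insertion is **private** if no same-family insertion lies within the window
in any other patient (either tissue) or in the same patient's other tissue.
Only tissue-specific insertions can be private — recurrence across
patients, or presence in the population panel, indicates a polymorphism
rather than a somatic event.

`total_insertions` counts a shared locus **once per patient** (not once per
tissue). This convention makes the shared fraction
`100 × (total − unique) / total` internally consistent with the per-patient
average `unique / n_patients`, and it is recorded in the summary object's
metadata.

## Population-frequency annotation

Each insertion is matched to the nearest same-family panel entry within the
window; unmatched insertions are `private`, matched ones are `low`
(0 < AF < 0.05) or `high` (AF ≥ 0.05). The 0.05 boundary itself goes to the
high bin (a closed upper bin); `high_closed = FALSE` flips it, since the
convention "> 0.05 high, < 0.05 low" leaves the boundary unassigned.

Comparing two three-bin histograms with a Kolmogorov–Smirnov test is
statistically degenerate (the ECDF has two steps). The primary test
therefore runs on the underlying matched allele frequencies with private
insertions mapped to AF 0 — the natural continuous embedding of the bins —
and a chi-square on the 3 × 2 bin-count table is reported alongside.
Neither is privileged; both are returned.

## The L1 excess statistic

Let `U_n`, `U_t` be unique all-TE insertion counts in normal and tumor, and
`L_n`, `L_t` the unique L1 counts. Under the null that L1 behaves like the
TE average, the expected L1 split is the all-TE split:

```
E_n = (L_n + L_t) · U_n / (U_n + U_t),   E_t = (L_n + L_t) − E_n
```

The observed `(L_n, L_t)` vs expected `(E_n, E_t)` 2 × 2 table is tested
with Fisher's exact test. Fisher requires integer tables, so expectations
are rounded half-up (the smallest perturbation); unrounded values are
reported too. The Fisher p-value is computed by direct enumeration of the
conditional hypergeometric distribution — the sum of probabilities of all
tables no more probable than the observed one (1e-7 relative tolerance for
floating-point ties) — and is cross-checked in the tests against an
independent `choose()`-based enumeration and `stats::fisher.test`. A
conventional alternative (L1 vs non-L1 by tissue) sits behind
`conventional = TRUE`; the observed-vs-expected construction is the primary
one because it conditions on the all-TE tissue imbalance.

## Genome-feature screening

Insertion points (1-based) are converted to 0-based and tested against
half-open intervals with precedence
**exonic > regulatory (enhancer) > intronic > intergenic**; published
breakdowns of this kind report the classes as mutually exclusive without
stating a precedence, and exonic-over-enhancer is the conservative choice
for a coding-disruption screen. Enhancers are linked to the gene with the
nearest strand-aware TSS within `tss_cap = 50000` bp (no linkage at cap 0).
Candidates are tumor-private insertions in exons or linked enhancers of
tumor-suppressor genes; with per-gene expression deltas supplied, a
down-regulated gene marks the candidate `concordant` — the insertion-plus-
silencing pattern expected of a driver event in a tumor suppressor.

One terminological note: the class counted alongside intronic and exonic in
such breakdowns is sometimes printed as "intragenic" where the arithmetic
implies the complement of the genic classes; `summarize_contexts()` always
reports it as `intergenic`, the non-exonic, non-regulatory, non-intronic
remainder.

## Expression and the EM quantifier

Expression comparisons are distribution-level: pooled per-tissue
`log10(count + 1)` values compared with the two-sample KS test (pseudocount
1 maps zero counts to 0; the handling of zeros is otherwise unstated in
common practice). Restricting L1 quantification to full-length intact
loci isolates transcription that must have initiated from a
transposition-competent element, rather than read-through of the many fixed
L1 fragments inside genes.

The EM quantifier implements the principle used by family-level TE
quantification tools: initialise locus abundances uniformly, E-step each
read fractionally to its candidate loci proportional to current abundances,
M-step abundances to the incoming fraction sums, iterate to a fixed point
(`tol = 1e-8` on the max abundance change, `max_iter = 200`). Total
abundance is conserved exactly and the log-likelihood is non-decreasing
(standard EM guarantees). It is deliberately simplified — instance-level,
no transcript-length normalisation, no mapping qualities — implementing the
stated assignment principle rather than emulating any specific tool's
objective.

## The synthetic cohort generator

The generator's defaults describe the study regime the analysis targets:

| parameter | default | rationale |
|---|---|---|
| `n_patients` | 9 | matched-pair cohort size of the targeted regime |
| `mean_depth` | 35 | ~35X whole-genome coverage |
| `n_germline_loci` | 850, Beta(0.7, 2) AFs | ≈330 carried germline loci per patient under diploid carrier probability `1−(1−AF)²`, putting the shared fraction near 81% |
| `somatic_rate_normal/tumor` | 11 per sample per family | with the L1 multiplier, E[unique] = 9 × (33 + 44) = 693 and a 1.33× tumor excess |
| `tumor_l1_multiplier` | 2 | two-fold somatic L1 excess in tumor |
| `caller_jitter_sd` | 15 bp (truncated ±100) | sub-window positional error; truncation keeps true pairs mergeable |
| `caller_fn_rate`, `caller_fp_rate` | 0.02, 0.05 | plausible error rates for the two-caller setting; the callers' true error rates are not published, so these are tunable knobs, not estimates |
| support mixture | real: NB(mean = depth, size 12); noise: NB(2, 2) | realises the observed bimodality; noise mass sits almost entirely below the 5-read cut-off |
| `expression$tumor_l1_log10_fc` | 1.0 | one-decade intact-L1 up-regulation in tumor |
| `expression$n_intact_l1` | 145 | size of the curated full-length intact L1 set |

Positions are drawn from a per-chromosome grid with ≥ 500 bp spacing
(`min_locus_spacing`), so the ±100 bp window can never fuse two distinct
truth loci and every evaluation oracle is unambiguous; false positives
occupy unused grid slots, hence are always ≥ 500 bp from truth. A single
seed fans out deterministically to per-stream child seeds (somatic counts,
positions, carriers, each caller, features, expression), making sub-streams
independently reproducible; identical configuration and seed give
byte-identical output.

**What passing tests do not show.** The generator emulates call tables, not
reads: no sequence content, target-site duplications, alignment artefacts,
reference bias, clonality/VAF structure, or correlated errors between
callers (real callers miss the same hard regions together, which would
lower consensus recall). Germline insertions are placed under
Hardy–Weinberg with panel-exact frequencies, so panel annotation on real
data — with population stratification and imperfect panel overlap — will be
noisier than the tests suggest. Precision/recall ≥ 0.9 on the default
cohort is a regression guard for this pipeline under its own error model,
not a claim about caller accuracy on real genomes.

## Verification sizes and statistical checks

Checks run at sizes chosen to make the oracles exact and the suite quick:
exhaustive-assignment equivalence on inputs of ≤ 50 calls; Fisher
enumeration against an independent oracle on **all** 2 × 2 tables with
total ≤ 40 (agreement to 1e-10); KS statistics against the brute-force
max-ECDF-gap on samples of ≤ 8; EM fixed points against a coarse-to-fine
grid search on ≤ 3-locus problems (within 1e-4, with each locus anchored by
a unique read so the maximum-likelihood solution is unique — fully
ambiguous problems have likelihood ridges on which EM and grid search may
legitimately settle on different points).

The replicate experiments for the L1-excess test run at somatic rate 22 per
sample per family (≈1400 somatic events per cohort): an a-priori power
calculation puts the test's power at ≈0.99 there versus ≈0.74 at the
default rate, so the 100-replicate rejection-rate check measures the
statistic, not Monte-Carlo luck. The type-I companion (multiplier 1) is
conservative by construction, because the expected row of the table is
derived from the same counts as the observed row. Generator defaults are
unaffected by this choice.

## Interfaces

The package's functions, this vignette and `scripts/acceptance.R` are the
intended interfaces; file formats (BED-derived TSV call and panel files,
BED12 gene models, BED enhancers, plain-text gene lists, YAML
configurations) are supported through the `read_*`/`write_*` functions, so
shell-based pipelines can interoperate without a dedicated command-line
binary.

## Known limitations

* Pairwise caller intersection only; no generalisation to > 2 callers.
* No genotyping, clonality or VAF modelling; early-embryonic and
  tumor-lineage somatic events are indistinguishable here.
* The EM quantifier is a principle-level implementation, not a drop-in
  replacement for production TE quantifiers.
* Greedy matching is optimal only under the spacing assumptions above.
* The exact 2 × 2 construction behind published L1-excess p-values is not
  recoverable from summary counts alone; the statistic is verified by
  property (power/type-I behaviour), not by reproducing a specific value.
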