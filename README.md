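# somaTE

Somatic transposable-element (TE) insertion and expression analysis for
matched normal/tumor cohorts.

Active human TE families — Alu, SVA and L1 — still copy themselves into new
genomic locations, and somatic insertions in tumor tissue can disrupt coding
or regulatory sequence of cancer genes. `somaTE` implements the downstream
analysis used to quantify that activity from whole-genome and transcriptome
sequencing of matched normal and primary-tumor samples, for researchers who
have per-caller TE insertion call sets (e.g. from MELT- or Mobster-style
discordant read-pair callers) and want a tested, reproducible path from raw
calls to driver candidates:

* **Consensus calling** — two callers' predictions are intersected: calls of
  the same family within ±100 bp are treated as the same insertion, and
  consensus calls are filtered to supporting-read counts in
  `[5, 4 × mean depth]` (the read-support distribution is typically bimodal,
  with a low-support noise mode removed by the lower cut-off).
* **Somatic classification** — per patient, insertions are partitioned into
  *shared* (present in both tissues, presumed germline), *normal-only* and
  *tumor-only*; tissue-specific insertions found in no other patient and
  absent from a population panel are *private* (candidate somatic events).
* **Population-frequency annotation** — insertions are matched to a
  reference panel of polymorphic TE loci (emulating the 1000 Genomes Phase 3
  catalogue) and binned as private (absent), low (AF < 0.05) or high
  (AF ≥ 0.05); normal and tumor frequency profiles are compared with a
  two-sample Kolmogorov–Smirnov test (plus a companion chi-square on the
  3 × 2 bin table).
* **L1 enrichment** — expected per-tissue unique-L1 counts are the all-TE
  normal:tumor split applied to the observed L1 total,
  `E_normal = L1_total · U_normal / (U_normal + U_tumor)`, and the observed
  vs expected 2 × 2 table is tested with Fisher's exact test (two-sided,
  by hypergeometric enumeration).
* **Driver screening** — tumor-private insertions are classified as
  exonic / regulatory (enhancer) / intronic / intergenic, and insertions in
  exons or enhancers of tumor-suppressor genes are flagged, with
  concordance against tumor down-regulation of the linked gene.
* **Expression** — TE and gene expression distributions are compared as
  log10(count + 1) with the KS test; a simple expectation-maximization
  quantifier fractionally assigns multi-mapped reads to candidate TE loci
  in proportion to estimated abundances, and the analysis can be restricted
  to full-length intact L1 loci.
* **Synthetic cohorts** — a fully parameterised generator produces truth
  sets, emulated two-caller outputs (positional jitter, false
  negatives/positives, bimodal support), panels, genome features and paired
  expression tables, so the whole pipeline is testable end to end without
  restricted sequencing data.

All user-facing functions take data frames and return tibbles, so steps
chain with the pipe; test-result objects support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

Simulate the default nine-patient cohort and run the pipeline:

```r
library(somaTE)

cohort <- simulate_cohort(cohort_config(seed = 1))
res <- analyze_cohort(cohort)
res$summary
#> TE cohort summary (shared loci counted once per patient)
#>   total insertions: 3571
#>   unique (private): 690 (normal 317, tumor 373)
#>   shared fraction: 80.7%
res$score
#> # A tibble: 1 × 5
#>      tp    fp    fn precision recall
#>   <int> <int> <int>     <dbl>  <dbl>
#> 1   681     9    25     0.987  0.965
```

About 81% of insertions are shared between a patient's two tissues
(germline), ~77 private insertions per patient remain, and the private set
recovers the simulated somatic truth with precision 0.99 / recall 0.97.
Tumor tissue carries an excess of unique L1 insertions:

```r
counts <- res$summary$counts
tab <- unique_count_table(
  res$summary$unique_normal, res$summary$unique_tumor,
  counts$n_unique[counts$family == "L1" & counts$tissue == "normal"],
  counts$n_unique[counts$family == "L1" & counts$tissue == "tumor"])
l1_excess_test(tab)
#> Unique L1 excess test (observed vs expected unique L1 by tissue)
#>          normal tumor
#> observed    103   186
#> expected    133   156
#> obs/exp: normal 0.776, tumor 1.191; p = 0.01404
```

Intact-L1 expression is up-regulated in tumor samples while the gene
background is not:

```r
expr <- cohort$expression
l1 <- expr[expr$class == "intact_l1", ]
glance(compare_expression(l1$count[l1$tissue == "normal"],
                          l1$count[l1$tissue == "tumor"]))
#> # A tibble: 1 × 4
#>   statistic p_value n_normal n_tumor
#>       <dbl>   <dbl>    <int>   <int>
#> 1     0.870       0     1305    1305

genes <- expr[expr$class == "gene", ]
glance(compare_expression(genes$count[genes$tissue == "normal"],
                          genes$count[genes$tissue == "tumor"]))
#> # A tibble: 1 × 4
#>   statistic p_value n_normal n_tumor
#>       <dbl>   <dbl>    <int>   <int>
#> 1   0.00556   0.944    18000   18000
```

The KS D = 0.87 for the 145 full-length intact L1 loci (9 patients pooled
per tissue) reflects the simulated ten-fold tumor up-regulation; gene
expression shows no distributional shift. See the vignette
(`vignettes/somatic-te-analysis.Rmd`) for the model details, parameter
choices and limitations.

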