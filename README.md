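# seqcontam

Detection, scoring, attribution and validation of cross-sample
contamination in bulk and single-cell RNA-seq.

## The problem

Genes that are both extremely highly expressed and tissue-enriched —
pancreatic acinar enzymes (*PRSS1*, *PNLIP*, *CELA3A*, *CLPS*), esophageal
keratins (*KRT4*, *KRT13*), insulin in beta cells — show up at low, variable
levels in samples of tissues that do not transcribe them. When that signal
forms coexpression clusters and tracks the calendar days on which the
native tissue was processed, it is carry-over of foreign template during
library preparation or sequencing. For differential-expression or eQTL work
this contamination masquerades as biology; `seqcontam` is for analysts who
need to detect it, quantify it, and trace it to its source.

## What the package computes

* **Cluster detection.** Per tissue: median-of-ratios size factors, a
  variance-stabilizing `log2(count/sf + 1)` transform, expression
  (mean > 5) and variance (> 4) screens, Kendall tau-b correlation of the
  variable genes, average-linkage clustering on `1 − τ`, and a dendrogram
  cut at the coarsest level where every cluster's mean pairwise τ clears

  `τ_crit = z₁₋α/(2m) · √(2(2n+5)/(9n(n−1)))`, `m = g(g−1)/2`,

  with marker-overlap labeling (`contamination` / `sex` / `unlabeled`).
* **Contamination scores.** Per sample `i`, panel of `J` marker genes,
  within tissue:

  `S_i = (1/J) Σ_j (x_ij − x̄_j) / Median_m |x_mj − x̃_j|`

  (mean-centered numerator, raw MAD denominator, tissue-internal strata).
* **Batch attribution.** Exact calendar-day flags against the source
  tissue's sequencing/isolation days; Wilcoxon rank-sum same-day vs
  off-day; proximity-in-days summaries; and the REML linear mixed model
  `score ~ seq_same_day + iso_same_day + tissue + (1 | subject)`.
* **Hidden-factor residualization.** TMM, low-TPM filter, rank
  inverse-normal transform, PCA hidden factors, and before/after same-day
  betas in SD units.
* **Genetic validation.** Expected allele fractions from native-tissue RNA
  (dosage fallback), dual-gate incongruency flagging (absolute deviation ≥
  0.05 and Bonferroni-corrected exact binomial at 1e-3), control-gene
  checks, and ranking of co-batched candidate donors carrying the foreign
  allele.
* **Single-cell quantification.** TP10K scaling (`TPM/100`), `log2(x+1)`,
  1000-TP10K doublet-like exclusion, percent contamination
  (`100 · recipient mean / source mean`), and source-present vs
  source-absent dataset contrasts.
* **Synthetic studies.** Negative-binomial multi-tissue generator with
  planted contamination fractions, batch calendars, donor identities,
  allele-count tables and ambient single-cell contamination — every
  downstream stage has recoverable ground truth.

## Worked example

```r
library(seqcontam)

cfg <- validate_config(list(simulate = TRUE, seed = 42, min_n = 8,
  simulate_args = list(samples_per_tissue = 30, n_background_genes = 120,
                       tissues = c("pancreas", "lung", "adipose"))))
report <- run_pipeline(cfg)
report
#> contamination_report
#>   pancreas: 0 cluster(s), 0 labeled contamination
#>   lung: 1 cluster(s), 1 labeled contamination
#>   adipose: 1 cluster(s), 1 labeled contamination
#>   rank-sum same-day vs off-day: p = 1.13e-08
#>   mixed model: beta_seq = 2.211, beta_iso = 0.216
#>   proximity: 100.0% of high-count off-day samples within window

report$clusters$lung
#>   cluster  gene mean_tau         label
#> 1       1 PRSS1 0.920599 contamination
#> 2       1  CLPS 0.920599 contamination
```

Reading this: in a simulated three-tissue study whose pancreas samples
natively express the four acinar markers, both recipient tissues develop a
coexpression cluster of those markers labeled `contamination` (here two of
the four markers cleared the variance screen in lung — which of the 3–4
markers cluster varies with the tissue's depth and contamination level).
Samples sequenced on a pancreas day score significantly higher
(rank-sum p ≈ 1e-08), the mixed model attributes the score shift to shared
sequencing days (β_seq ≫ β_iso), and every high-count off-day sample sits
within the 4-day proximity window of a pancreas sequencing day.

The single-cell side, on a simulated pancreas-like dataset with a planted
2% ambient fraction:

```r
sc <- simulate_sc_dataset(sc_simulation_config(seed = 42))
percent_contamination(sc$cells, "INS", "beta", "endothelial")
#> contamination_estimate [sim_sc]: INS in endothelial = 1.982% of beta (n = 295, 5 excluded)
```

The estimate recovers the planted ambient fraction; the 5 excluded cells
are the planted doublets above 1000 TP10K.

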