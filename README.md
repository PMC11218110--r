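# pdblood

Blood-based biomarker discovery for neoadjuvant PD-1 blockade response in
non-small-cell lung cancer (NSCLC).

Checkpoint-inhibitor response is usually assessed from tumor tissue, but
peripheral blood is far easier to sample before and during therapy. This
package implements, as a tested and reusable pipeline, the analysis chain
used to mine blood RNA-seq and blood-derived germline variant calls for
response markers:

- **Immune-cell deconvolution** by marker-gene abundance scoring: candidate
  markers for each immune cell subset are filtered by their average pairwise
  Pearson correlation across samples on log2(FPKM + 1) (retain genes with
  average r > 0.60 and Fisher-combined p < 0.01, targeting 10–20 final
  markers per subset), and the abundance score of a subset in a sample is
  the simple average of its markers' log2 expression
  (`select_markers()`, `abundance_scores()`, `compare_scores()`).
- **Differential expression and set algebra**: median-of-ratios
  normalization, per-gene Welch or paired t-tests on log2 counts with
  Benjamini–Hochberg adjustment, and the DEG rule |fold change| > 2 (1.2
  for cell lines) *and* FDR p < 0.05; Common/Unique gene sets across
  contrasts; hierarchical-clustering stratification of pre-treatment
  samples on responder-unique DEGs (`de_test()`, `deg_set_algebra()`,
  `stratify_by_degs()`); qPCR relative expression by 2^−ΔΔCt (`ddct()`).
- **Mutation markers**: PASS-variant filtering, gene ranking by mean
  driver/pathogenicity scores with a gene-level FDR, responder
  (PTCH1, DNMT3A, PTPRS, JAK2) vs non-responder (TNFAIP3, BRCA1, ASXL1,
  GATA2) panel stratification, and TMB comparison (`filter_pass()`,
  `rank_genes()`, `stratify_cohort()`, `tmb_by_subgroup()`).
- **Survival**: Kaplan–Meier product-limit curves, the two-group log-rank
  test and single-covariate Cox proportional-hazards regression
  (Newton–Raphson on the partial likelihood, Efron or Breslow ties),
  implemented from first principles (`km_estimate()`, `logrank_test()`,
  `cox_fit()`).
- **Synthetic data with ground truth** for every stage — cell-type
  signatures with enriched markers, Dirichlet pseudo-bulk mixtures,
  negative-binomial cohorts with planted fold changes and paired pre/on
  samples, variant tables with planted panels, and exponential survival
  with subgroup hazard ratios (`simulate_*()`), so the whole pipeline is
  testable without any external download.

`run_pipeline()` chains all stages on simulated data and emits a
machine-readable JSON report.

## Worked example

```r
library(pdblood)

## three-group cohort (5 healthy controls, 12 responders, 17 non-responders,
## paired pre/on samples) with planted DEGs
sim  <- simulate_cohort(cohort_design(seed = 42))
norm <- normalize_counts(sim$expr)

keep    <- is.na(sim$meta$timepoint) | sim$meta$timepoint == "pre"
resp    <- keep & sim$meta$group %in% c("HC", "responder")
nonresp <- keep & sim$meta$group %in% c("HC", "non_responder")
deg_r <- de_test(norm[, resp], sim$meta[resp, ], c("HC", "responder"))
deg_n <- de_test(norm[, nonresp], sim$meta[nonresp, ], c("HC", "non_responder"))
sets  <- deg_set_algebra(list(responder = deg_r, non_responder = deg_n))
sets$counts
#>               common     unique_responder unique_non_responder
#>                    0                   91                   91

## responder-unique DEGs stratify the pre-treatment cancer samples
pre <- keep & sim$meta$group != "HC"
st  <- stratify_by_degs(norm[, pre], sets$unique$responder, k = 2,
                        true_labels = sim$meta$group[pre])
c(ari = st$ari, purity = st$purity)
#> ARI: 1  purity: 1

## mutation-panel stratification and survival
ms  <- simulate_variants_and_survival(n_patients = 300, seed = 42)
lab <- stratify_cohort(filter_pass(ms$variants), patients = ms$survival$patient)
s   <- merge(ms$survival[, 1:3], lab)
s2  <- s[s$subgroup %in% c("responder", "unaltered"), ]
fit <- cox_fit(s2$time_months, s2$event, as.integer(s2$subgroup == "responder"))
lr  <- logrank_test(s2$time_months, s2$event, s2$subgroup)
#> HR 0.484 (95% CI 0.309-0.758), log-rank p = 0.0012 **
```

Of 2000 simulated genes, 100 were planted per contrast; 91 of the
responder-vs-healthy planted genes pass the DEG rule and, being absent from
the non-responder contrast, land in the responder-unique set. Clustering
the 29 pre-treatment samples on those genes separates responders from
non-responders perfectly (ARI and purity 1). In the 300-patient mutation
cohort the responder-panel subgroup was simulated at a true hazard ratio of
0.5 versus unaltered patients; the Cox fit recovers 0.48 with a confidence
interval covering the truth, and the log-rank test rejects equality of the
survival curves.

## Package layout

- `R/synthetic.R` — generators for signatures, pseudo-bulk, cohorts,
  variants and survival
- `R/deconvolution.R`, `R/diffexpr.R`, `R/mutation.R`, `R/survival.R` —
  the four analysis stages
- `R/io.R` — TSV/VCF readers and writers; `R/pipeline.R` — configuration
  and the end-to-end run
- `vignettes/blood-biomarker-pipeline.Rmd` — the methods vignette
  (model, assumptions, parameter choices, limitations)
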