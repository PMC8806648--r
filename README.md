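# itaemt

Tumor-infiltrating T cells fight tumors; epithelial–mesenchymal transition
(EMT) programs blunt that response. `itaemt` implements, as a tested and
reusable R pipeline, a procedure for combining **infiltrating T-cell
abundance (ITA)** with **EMT-related gene expression** into a prognostic
factor for bulk tumor transcriptomes (the motivating setting is colon
cancer, but nothing is tissue-specific):

1. **Marker-based scoring.** T-cell marker genes are selected from an
   immune-cell signature matrix (22 cell types/states, LM22-style): each
   gene row is normalized by its mean across cell types, and a gene is a
   marker iff its normalized mean over the T-lineage columns exceeds 2.
   Then, per sample,

   - `ITA_s = mean_{g ∈ markers} log2(x_gs + 1)`
   - `EMT_s = mean_{g ∈ EMT set} log2(x_gs + 1)` (200-gene hallmark EMT set)

2. **Purity residualization.** Bulk scores confound biology with sample
   composition. Stromal and immune scores are computed by single-sample
   gene-set enrichment (ssGSEA, rank-weight exponent `α = 0.25`), tumor
   purity is obtained from the cosine transform
   `purity = cos(0.6049872018 + 0.0001467884 · (stromal + immune))`,
   and each score is replaced by its residual from the OLS regression
   `score ~ 1 + log(1 − purity)`.

3. **Survival analysis.** Cox proportional-hazards models on the adjusted
   scores with hazard ratios scaled to the interquartile contrast,
   `HR_IQR = exp(β · (q75 − q25))`, with two-sided 95% Wald intervals;
   median dichotomization and the 2×2 EMT×ITA grouping compared by
   Kaplan–Meier curves and log-rank tests; per-EMT-gene Cox screening
   controlling for ITA at `p < 0.05`; and validation of the selected genes
   in a second cohort with ITA recomputed there.

Because the original cohorts (TCGA colon cancer, GEO validation) cannot be
redistributed, the package ships a **synthetic cohort generator**
(`simulate_cohort()`) producing compartment-mixture expression
(tumor/immune/stromal), purity-correlated ITA/EMT signal, and
proportional-hazards survival with known coefficients, so every stage of the
pipeline is testable end to end with known ground truth. Real matrices can
be substituted at any stage through the readers (`read_expression_matrix()`,
`read_clinical_table()`, `read_signature_matrix()`, `read_gmt()`).

The package is aimed at computational biologists studying tumor–immune
interactions who want the scoring/adjustment/survival machinery as plain
tibble-in, tibble-out functions.

## Worked example

```r
library(itaemt)

res <- run_pipeline(sim_config(seed = 2024), purity = "truth")
res
#> <itaemt_pipeline>
#>   markers selected: 159
#>   samples scored/adjusted: 469
#>   raw EMT-ITA r = 0.418; adjusted r = 0.600
#>   4-group log-rank p: raw 0.001754, adjusted 0.0001179
#>   genes selected: 199; validated in cohort 2: 25

tidy(res$cox_fit)
#> # A tibble: 2 × 8
#>   term    beta    se   wald_p   iqr hr_iqr ci_low ci_high
#>   <chr>  <dbl> <dbl>    <dbl> <dbl>  <dbl>  <dbl>   <dbl>
#> 1 emt_z  0.672 0.102 5.05e-11  1.44  2.63   1.97    3.51
#> 2 ita_z -0.497 0.106 2.57e- 6  1.25  0.538  0.415   0.696
```

Reading the output: 159 T-cell marker genes pass the selector; the raw
EMT–ITA correlation (0.42) rises to 0.60 after purity residualization
(tumor purity pushes the two raw scores in opposite directions, masking
their shared biology); a top-quartile adjusted-EMT patient carries about
2.6 times the hazard of a bottom-quartile one (`hr_iqr`), while
top-quartile adjusted ITA roughly halves the hazard; and the four
EMT×ITA groups separate much more cleanly after adjustment (log-rank
p = 1.2e-4 vs 1.8e-3). On these synthetic cohorts nearly all EMT-set
genes are individually prognostic because they share one latent EMT
program; real cohorts are sparser (see the vignette's limitations).

Each stage is also exposed on its own —
`select_t_cell_markers()`, `ita_score()`/`emt_score()`, `enrich_all()` +
`correlate_with_score()`, `purity_from_expression()`,
`adjust_for_purity()`, `fit_cox()`/`hr_iqr()`, `four_group()` +
`km_logrank()`, `rank_emt_genes()`/`validate_genes()` — and plots are
available via `autoplot()` on Kaplan–Meier results,
`plot_score_scatter()`, `plot_enrichment_correlation()` and
`plot_gene_ranking()`.

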