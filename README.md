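# tmespatial

Spatial statistics for the tumor immune microenvironment from multiplex
immunohistochemistry (mfIHC) cell tables.

Pathology workflows that image tissue-microarray (TMA) cores with
multiplexed markers produce per-cell tables: coordinates in microns plus
binary calls for CD3, CD8, FoxP3, CD163, pancytokeratin, PD-L1, granzyme B
and Ki67. `tmespatial` turns such tables into cohort-level inference about
how immune and tumor cells are *arranged*: who sits next to whom, who is in
contact range, and how strongly two populations mix — and whether that
arrangement differs between patient groups defined by HLA-DR (MHC class II)
expression. It is aimed at computational pathology and immuno-oncology
groups analysing mfIHC TMA cohorts.

## What it computes

Cells are phenotyped by marker logic (CD3⁺CD8⁺ CTL, CD3⁺CD8⁻FoxP3⁻ helper T,
CD3⁺CD8⁻FoxP3⁺ Treg, CD163⁺ APC, PanCK⁺ epithelial, else other), and each
core contributes, per ordered phenotype pair (x → y):

- **mean nearest-neighbor distance** (µm);
- **engagement**: the percent of x cells with ≥ 1 y cell within 40 µm
  center-to-center, plus the mean number of simultaneous contacts;
- **cross-type G-function AUC**: the nearest-neighbor distance distribution
  G<sub>x→y</sub>(r) = P(nearest y within r of an x cell), estimated with a
  Kaplan–Meier edge correction that censors each observation at the cell's
  distance to the core boundary, and summarised by the trapezoidal area
  under G over r ∈ [0, 60 µm]. Under complete spatial randomness
  G(r) = 1 − exp(−λ<sub>y</sub>πr²), which the package uses as its
  simulation oracle;
- **composition**: phenotype fractions, activated fractions (GZMB⁺Ki67⁺
  CTLs, Ki67⁺ helper T), CTL/Treg ratio, with PD-L1± stratified variants.

Cores average to patients (equal weight per core by default; pooling
available), patients are stratified around the cohort-mean HLA-DR positive
surface area, and every metric is compared between strata with a
Shapiro–Wilk-gated ANOVA/Wilcoxon battery plus Pearson correlation against
HLA-DR, with Benjamini–Hochberg adjustment within metric families. A
synthetic cohort generator (Poisson and Thomas-style clustered point
patterns in circular cores, with configurable stratum effects) makes every
stage testable without patient data.

## Worked example

```r
library(tmespatial)

cfg    <- synthetic_config(n_patients = 40, seed = 7)   # two-stratum cohort
sim    <- generate_cohort(cfg)
cohort <- stratify_cohort(assign_phenotypes(sim$cohort))
print(cohort)
#> <tme_cohort> 40 patients, 120 cores, 40565 cells
#>   HLA-DR strata: 19 HIGH / 21 LOW (threshold 8.382%)
#>   phenotypes: TCELL_HELPER=1290 TCELL_CTL=526 TCELL_TREG=187 APC=2988 EPITHELIAL=5013 OTHER=30561

cs  <- summarize_cohort(cohort)          # per-core spatial metrics
ps  <- aggregate_patients(cs)            # per-patient means over cores
bat <- run_comparison_battery(ps, cohort$patients)

sel <- c("mean_nn|TCELL_HELPER|APC", "engagement_pct|TCELL_HELPER|APC",
         "fraction_pct|IMMUNE", "g_auc|TCELL_HELPER|APC")
bat$comparisons[bat$comparisons$metric %in% sel,
  c("metric", "group_high_mean", "group_low_mean", "test", "p_raw", "p_adjusted")]
#>                           metric group_high_mean group_low_mean     test     p_raw p_adjusted
#>  engagement_pct|TCELL_HELPER|APC           58.72         32.296 WILCOXON 3.836e-05  2.685e-04
#>              fraction_pct|IMMUNE           15.54          9.362 WILCOXON 1.496e-04  7.479e-04
#>           g_auc|TCELL_HELPER|APC           24.13         12.838 WILCOXON 6.112e-05  1.222e-04
#>         mean_nn|TCELL_HELPER|APC           41.68         68.210 WILCOXON 3.034e-05  9.706e-05
```

Reading the rows: in the HLA-DR-high stratum, helper T cells sit on average
41.7 µm from their nearest APC versus 68.2 µm in the low stratum; 58.7% vs
32.3% of helper T cells have an APC within contact range; immune cells make
up 15.5% vs 9.4% of all cells; and the helper-T/APC mixing AUC is 24.1 vs
12.8 µm — shorter distances, more engagement, denser infiltrate and
stronger mixing with high MHC-II, each with its raw and family-wise
BH-adjusted p-value. (These are the generator's built-in effect directions
being recovered from the simulated coordinates.)

The same pipeline runs from the shell on any cell-table CSV
(`inst/cli/tmespatial.R simulate|analyze`), writing per-core and per-patient
summary CSVs, comparison/correlation CSVs, and a plain-text report.

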