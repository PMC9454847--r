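---
title: "Spatial statistics for multiplex-IHC tumor microenvironments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial statistics for multiplex-IHC tumor microenvironments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmespatial)
```

## The scientific setting

Multiplex fluorescent immunohistochemistry (mfIHC) on tissue-microarray
(TMA) cores produces, after segmentation and marker thresholding upstream,
a table of cells with micron-scale coordinates and binary marker calls.
`tmespatial` consumes such tables and asks how the spatial organisation of
immune and tumor cells differs between patient groups — here, groups defined
by MHC class II (HLA-DR) expression, measured as the percent of core surface
area staining positive. The biological hypotheses are about *proximity* and
*mixing*: do helper T cells sit closer to antigen-presenting cells (APCs)
when HLA-DR is abundant; are cytotoxic T lymphocytes (CTLs) more engaged
with tumor epithelium; is the infiltrate larger and more activated?

All statistics in the package are distances or functions of distances, so
results are invariant under translation and rotation of the coordinate
frame; the image origin and y-axis direction are irrelevant.

## Phenotyping

Cells are assigned one of six mutually exclusive lineage phenotypes from the
eight marker flags:

* CD3+CD8+ — cytotoxic T cell (CTL)
* CD3+CD8-FoxP3+ — regulatory T cell (Treg)
* CD3+CD8-FoxP3- — helper T cell
* CD3-CD163+ — antigen-presenting cell (APC)
* CD3-CD163-PanCK+ — epithelial (tumor) cell
* all lineage markers negative — other

GZMB, Ki67 and PD-L1 are *state* markers: they never change the lineage
call, but metric definitions may filter on them (an "activated CTL" is
GZMB+Ki67+; PD-L1 stratifies epithelial targets). Biologically
contradictory co-positivity (e.g. CD3+PanCK+, usually a segmentation
artifact) is resolved by the lineage precedence CD3 > CD163 > PanCK,
because the T-cell definition rests on CD3 alone; conflicts are counted per
core and logged so heavily affected cores can be reviewed.

## Stratification

Because no biologically validated HLA-DR cutoff exists, patients are split
at the *cohort mean* of their per-patient HLA-DR surface-area percent (the
mean over a patient's cores). Values at or above the threshold are HIGH —
the tie rule is arbitrary but deterministic, and exact ties have measure
zero on real measurements. Unequal group sizes are expected and accepted.

## Per-core spatial metrics

For an ordered phenotype pair (reference, target), computed per core:

* **Mean nearest-neighbor (NN) distance** — the mean over reference cells
  of the Euclidean distance to the closest target cell (self-pairs excluded
  when the sets coincide).
* **Engagement** — the percent of reference cells with at least one target
  cell within 40 µm center-to-center (boundary inclusive; 40 µm is roughly
  two cell diameters and is the conventional contact radius for this assay).
  Among engaged cells, the mean number of simultaneous target contacts is
  also recorded.
* **Cross-type G-function and its AUC** — see below.
* **Composition** — phenotype fractions of all cells, activated fractions
  within a phenotype, and the CTL/Treg count ratio.

A metric whose reference or target set is empty is *missing*, never zero
(except composition fractions, which are legitimately zero); missingness
propagates explicitly so that downstream tests drop exactly those units.

## The cross-type G-function with Kaplan–Meier edge correction

The cross-type nearest-neighbor distance distribution
$G_{x\to y}(r) = P(\text{nearest } y \text{ cell within } r \text{ of an }
x \text{ cell})$ summarises mixing of two populations. Under complete
spatial randomness (CSR) of the targets with intensity $\lambda_y$,

$$G(r) = 1 - e^{-\lambda_y \pi r^2},$$

which the package exposes as `poisson_g()` — used as the simulation oracle,
not as the estimator.

A TMA core is a bounded disc, and a reference cell near the boundary may
have its true nearest neighbor outside the observed window; the naive
empirical CDF of observed NN distances is therefore biased downward. The
package estimates $G$ with the product-limit (Kaplan–Meier) estimator of
the distance distribution under boundary censoring: each reference cell
contributes observation time $\min(d_i, c_i)$ and event indicator
$d_i \le c_i$, where $d_i$ is its observed NN distance and $c_i$ its
distance to the window boundary. The key geometric fact making this exact
is that any point closer to the reference cell than the boundary is inside
the window — so whenever $d_i \le c_i$, the observed neighbor *is* the true
nearest neighbor, and otherwise all that is known is $d_i^{true} > c_i$.
Because the target process is homogeneous, censoring (a function of
position only) is independent of the true NN distance, and the estimator is
consistent. In the package's calibration experiment (100 CSR cores,
$\lambda = 0.002\,\mu m^{-2}$, 300 µm disc) the seed-averaged KM curve
deviates from the closed form by under 0.006 in sup-norm while the raw
ECDF carries a bias near 0.01 — per-core curves are noisy (pointwise SD
about 0.027 in the steep region), which is why the calibration pools and
averages many cores rather than judging single cores.

The curve is evaluated on a fixed grid of 0–60 µm in 1 µm steps —
sub-micron resolution would be below a cell diameter, and a shared grid
makes AUCs comparable across cores — and summarised by the trapezoidal
**AUC over [0, 60 µm]** (in µm, bounded by 60): a faster-rising G, i.e.
stronger mixing, gives a larger AUC.

## Core-to-patient aggregation

Patients contribute up to three cores by design. The default aggregation
gives each valid core equal weight (unweighted mean over cores where the
metric is non-missing), reflecting the triplicate design. An alternative
`"pooled"` aggregation weights cores by the metric's denominator (reference
count for distances/engagement, total cells for fractions, summed counts
for ratios), which reproduces exactly the metric computed on the patient's
pooled cells — except for the G AUC, where a denominator-weighted mean of
per-core AUCs is used as a pragmatic stand-in for a pooled product-limit
fit. The choice is exposed in `run_config(aggregation=)` because the right
answer depends on whether cores are viewed as replicate measurements or as
arbitrary tiles of one tissue.

## The comparison battery

Each patient-level metric is compared between HLA-DR strata with a
normality-gated test: both groups are screened by Shapiro–Wilk at
$\alpha = 0.05$, and only if both pass is a two-sided two-group one-way
ANOVA used (pooled variance; identical to the squared pooled-variance t
statistic); otherwise the Wilcoxon rank-sum test (exact for combined
$n \le 20$ without ties, else normal approximation with continuity and tie
correction). Requiring *both* groups to pass is the conservative reading of
"non-normal data get the rank test". Groups with fewer than three
non-missing values are reported as not computable. Each metric is also
correlated (Pearson, two-sided t transform) with the continuous HLA-DR
surface-area percent; both $r$ and $r^2$ are reported since conventions for
reporting "R" differ between software packages.

Categorical contrasts use Fisher's exact test with the probability-ordering
two-sided convention (sum of hypergeometric probabilities of tables no more
probable than the observed one); a zero margin yields $p = 1$ with a
warning, since such a table carries no information. Multiplicity is handled
with Benjamini–Hochberg step-up adjustment applied *within each result
family* (distances, engagement, infiltration, mixing, activation) — the
five reporting panels define natural hypothesis families, and adjusting
across unrelated panels would couple unrelated questions. Note that BH is
not idempotent: re-adjusting already-adjusted values inflates interior
order statistics (the step-up multiplier $m/j$ exceeds 1), so adjusted
p-values are computed exactly once, from raw p-values.

## The synthetic cohort generator

No patient-level mfIHC dataset ships with the package, so every pipeline
stage is exercised against a generator whose statistical structure matches
the analysis assumptions:

* Each phenotype is a homogeneous Poisson point pattern in the 300 µm core
  disc (counts Poisson with mean $\lambda \pi R^2$, positions uniform).
* Attraction between phenotypes is modelled parent–offspring
  (Thomas-style): a binomial fraction of an offspring phenotype's cells are
  Gaussian displacements (sd $\sigma$) from uniformly chosen parent cells,
  resampled until inside the disc so the window stays exact; the remainder
  are CSR. Counts are drawn before positions, so clustering moves cells but
  never changes the count distribution. This is the simplest mechanism that
  elevates the cross-type G in an analytically understood way: as
  $\sigma \to \infty$ the pattern converges back to CSR.
* Activation/checkpoint flags are independent Bernoulli per cell given
  phenotype and stratum.
* HLA-DR surface area is Gaussian per stratum, truncated to [0, 100], drawn
  per patient and copied to its cores (stratification is a patient-level
  construct).

Default parameters (chosen once, as study conditions): total intensity
$1.2\times10^{-3}\,\mu m^{-2}$ — about 340 cells per core. This is sparser
than a real tumor core; it is chosen so that 40 µm engagement probabilities
sit mid-range under CSR. Real epithelium grows in tight nests that exclude
immune cells, which keeps real engagement percentages low despite high cell
density; the generator has attraction but no exclusion/nest geometry, so at
realistic densities engagement would saturate near 100% for every stratum
and direction effects would vanish. The HIGH stratum has roughly twice the
immune intensity of LOW (immune fraction about 17% vs 8% of cells), a
helper-T-to-APC attraction at $\sigma = 25$ µm (neighborhood mixing scale)
with clustered fraction 0.5 vs 0.1, a CTL-to-epithelium attraction at
$\sigma = 15$ µm (contact scale) with the same fractions, and higher
activation rates (CTL GZMB/Ki67 0.6 vs 0.45 each; helper-T Ki67 0.15 vs
0.08; these are set above histology-typical values so that activated-subset
metrics retain usable cell counts at the generator's deliberately sparse
densities). HLA-DR is 14 ± 6% vs 4.5 ± 2.5%, consistent with a
low-expression metastatic setting (cohort mean near 9%). Effect
*directions* mirror what is reported for MHC-II-high tumors; effect
*magnitudes* are not calibrated to any published cohort, so passing
direction-recovery tests demonstrates that the pipeline detects effects of
this kind, not that the generator reproduces a particular dataset. A
`"null"` variant copies the LOW parameters to both strata for
type-I-error studies.

## Validation experiments and problem sizes

The test suite validates each operation against an independent oracle
(exhaustive $O(n^2)$ enumeration for distances and engagement;
`survival::survfit` for the product-limit fit; hand step-up for BH;
hypergeometric enumeration for Fisher; the closed form for CSR), and runs
four cohort-scale experiments at fixed seeds:

* **Estimator calibration** — 100 pooled CSR cores at
  $\lambda = 0.002\,\mu m^{-2}$: pooled KM sup-error below 0.05 and below
  the raw ECDF's, and seed-averaged KM closer to theory than seed-averaged
  ECDF.
* **Type-I error** — 200 null cohorts (60 patients, one core each,
  identical strata), battery on four representative metrics spanning the
  families; per-metric false-positive rates must lie within 99% binomial
  bounds of the nominal 0.05 over the 200 independent replicates.
  (Per-metric, because p-values of different metrics within one cohort are
  correlated; pooling them would make a binomial bound invalid.)
* **Effect-direction recovery** — 20 cohorts of 100 patients with the
  default stratified effects: the HIGH-vs-LOW sign of the helper-T-to-APC
  distance (lower), T/APC and helper-T/APC engagement (higher), immune
  fraction (higher), helper-T/APC G AUC (higher) and activated-CTL/EC
  engagement (higher) must be recovered in at least 95% of replicates, and
  the headline distance comparison must also be significant at raw
  p < 0.05 in at least 95%.
* **Determinism** — simulate + analyze twice from one seed yields
  byte-identical result tables.

These sizes (60- and 100-patient cohorts, 1–3 cores, ~340 cells per core)
were chosen as the smallest designs at which the experiments have adequate
statistical power; they are stated here so the reported error rates can be
read in context.

## Numerical and degenerate-input conventions

* Coordinates are microns; round-tripping through the CSV format preserves
  them to 0.01 µm.
* Windows: a circle (or rectangle via the API); when a table carries no
  geometry the window is a 300 µm circle at the cell centroid, expanded
  minimally to contain every cell.
* KM estimator with no events (all censored) returns $G \equiv 0$; a
  coincident target (distance 0) gives $G(r) = 1$ for all $r > 0$.
* An exact tie at the stratification mean goes HIGH; an all-equal cohort
  stratifies everyone HIGH with a warning.
* Constant samples fail the normality gate (the Shapiro–Wilk statistic is
  undefined) and route to the rank-sum branch; two identical groups with
  variance give ANOVA F = 0, p = 1.
* Wilcoxon switches from exact to corrected-normal inference at combined
  n > 20 or in the presence of ties.

## Known limitations

* The generator omits tumor-nest geometry, stromal bands, and inhomogeneous
  intensity; real cores violate CSR in ways beyond parent–offspring
  clustering, so test passes bound estimator behaviour only under the
  stated models.
* The pooled aggregation of G AUC is a weighted mean of per-core AUCs, not
  a pooled product-limit fit.
* The G machinery is 2-D and homogeneous; no inhomogeneous (intensity-
  reweighted) correction and no Ripley K analogue are provided.
* Whether published analyses averaged per core or pooled cells per patient
  is generally unstated; both are available, and defaults use the per-core
  mean.
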