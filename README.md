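# mifquant

Quantitative and spatial profiling of the tumor immune microenvironment
(TIME) from multiplex immunofluorescence (mIF) and immune gene expression,
for studies contrasting HPV-positive and HPV-negative oropharyngeal
squamous cell carcinoma (OPSCC) and relating immune features to
disease-free survival (DFS).

The package is aimed at translational immuno-oncology analysts working from
*segmented* mIF cell tables (one row per cell: coordinates in µm, binary
marker calls, tumor/stroma compartment) and immune-panel count matrices; it
starts downstream of imaging, unmixing and segmentation.

## What it computes

* **Phenotyping** — marker-rule phenotype labels (CTL = CD8⁺, Treg =
  FoxP3⁺CD8⁻, M2-TAM = CD68⁺CD163⁺, T_RM = CD8⁺CD103⁺, PD-L1⁺ tumor cells,
  …), non-exclusive by design, plus tumor-nest/stroma compartment
  assignment from polygon geometry.
* **Quantification** — compartmentalized densities (cells/mm², pooled count
  over pooled area), percentages among parent populations, population
  ratios (e.g. CD8⁺/FoxP3⁺ within tumor areas).
* **Spatial proximity** — the two per-field statistics used in mIF
  proximity analysis: the mean nearest-neighbor distance between phenotype
  pairs, and the count-within statistic

  `pct(ref → query, r) = 100 · #{ref cells with ≥1 query cell at distance ≤ r} / #{ref cells}`

  with r = 20 µm by default, boundary inclusive, no edge correction.
* **Expression profiling** — housekeeping geometric-mean normalization,
  log2 transform, per-gene OLS differential expression on the HPV indicator
  (≡ equal-variance t-test), Benjamini-Hochberg adjustment, DEG calls at
  |log2FC| > 1 and adjusted p < 0.05, and mean-log2 signature scores.
* **Outcome analysis** — median dichotomization (ties → low), Kaplan-Meier,
  log-rank (Mantel-Cox), univariate Cox with Efron ties (HR, 95% CI), and a
  per-variable survival screen.
* **Synthetic cohorts** — a fully seeded generator (Poisson cells in
  nest/stroma geometry, negative-binomial counts with injected DE genes,
  exponential survival driven by immune covariates) whose shipped
  calibration reproduces the published HPV contrasts; it backs every
  validation in the test suite.

## Worked example

```r
library(mifquant)

# one HPV-positive and one HPV-negative synthetic metastasis, 5 fields each
les_pos <- generate_lesion(default_calibration(), "positive", "metastasis",
                           "TN01_met", n_fields = 5, seed = 42)
les_pos$cells <- assign_phenotypes(les_pos$cells)
les_neg <- generate_lesion(default_calibration(), "negative", "metastasis",
                           "TN02_met", n_fields = 5, seed = 43)
les_neg$cells <- assign_phenotypes(les_neg$cells)

cell_density(les_pos, "CTL", "tumor")        # 283.8 cells/mm2 (HPV+)
cell_density(les_neg, "CTL", "tumor")        #  40.7 cells/mm2 (HPV-)
pct_within_radius(les_pos, "tumor", "CTL")   # 29.5 % of tumor cells near a CTL
pct_within_radius(les_neg, "tumor", "CTL")   #  4.6 %
nn_mean_distance(les_pos, "tumor", "CTL")    # 29.5 um mean NN distance
nn_mean_distance(les_neg, "tumor", "CTL")    # 79.6 um

# expression: 770-gene panel, 24 vs 15 samples, 30 injected DE genes
groups <- setNames(rep(c("positive", "negative"), c(24, 15)), sprintf("P%02d", 1:39))
ex <- generate_expression(expression_params(log2fc_range = c(1.5, 2)), groups, seed = 7)
de <- differential_expression(log2_transform(normalize_housekeeping(ex$matrix)), groups)
sum(de$is_deg)                               # 30 DEGs called
sum(de$gene[de$is_deg] %in% ex$truth$gene)   # all 30 are true injected genes
```

The HPV-positive lesion is densely infiltrated (CD8⁺ density ~7× higher
intra-tumorally), which the proximity statistics translate into ~30% of
tumor cells having a cytotoxic T cell within 20 µm versus ~5% in the
HPV-negative lesion — the spatial signature of a "hot" versus "cold" TIME.
On the expression side the pipeline recovers exactly the injected
differential-expression structure at the standard DEG thresholds.

An end-to-end run (simulation → phenotyping → quantification → proximity →
DE → comparisons → survival screen, with a reproducibility manifest):

```r
run_pipeline("out/", seed = 7, n_pos = 4, n_neg = 4, n_fields = 5)
```

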