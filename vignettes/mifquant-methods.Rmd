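---
title: "Methods: quantitative and spatial TIME profiling with mifquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative and spatial TIME profiling with mifquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifquant)
```

# Scope and data model

`mifquant` quantifies the tumor immune microenvironment (TIME) of
oropharyngeal squamous cell carcinoma from two data layers:

* **Segmented multiplex-immunofluorescence (mIF) cell tables** — one row per
  cell with field ID, x/y centroid coordinates in micrometres, binary marker
  calls for one of two panels (a 9-color panel: CD68, CD8, FoxP3, CD163,
  CD103, PD-1, PD-L1, pan-cytokeratin; a 6-color panel: CTLA-4, CD4, CD8,
  HLA-I, pan-cytokeratin), and a tumor/stroma compartment label. The package
  starts downstream of spectral unmixing, segmentation and intensity
  thresholding: marker calls are consumed as binary.
* **Immune-panel gene counts** — a genes x samples raw count matrix
  (nominally 770 genes, 40 of them housekeeping) with per-sample metadata
  (HPV status, sex, disease-free survival).

Coordinates use per-field local frames, origin at the field top-left, in
micrometres; densities convert to cells/mm^2 by dividing areas by 1e6. The
default field is 650 x 500 um (configurable) — 20x-objective imaging fields
are of this order, and none of the statistics depends on the exact value
beyond edge effects discussed below.

A tumor is classified HPV-positive only on *double positivity*: HPV DNA
detected and p16INK4a staining in >= 70% of tumor cells, with the threshold
applied inclusively (`classify_hpv_status()`).

# Phenotyping and compartments

Phenotype labels are conjunctions of required-positive and required-negative
markers (`phenotype_rule()`), evaluated non-exclusively: a CD8+CD103+PD-1+
cell is simultaneously a CTL, a tissue-resident memory (TRM) cell, a
CD8+PD-1+ cell and a CD8+CD103+PD-1+ cell. The shipped 9-color rules are:
tumor = CK+; CTL = CD8+; Treg = FoxP3+ CD8-; macrophage = CD68+; M1-TAM =
CD68+CD163-; M2-TAM = CD68+CD163+; TRM = CD8+CD103+; the PD-1+ CTL subsets;
and PD-L1+ tumor/macrophage variants. Two conventions here are package
decisions rather than reported definitions: Tregs exclude CD8+ cells (to
avoid double-counting activated CTLs as regulatory), and on the 6-color
panel Th cells are CD4+ CK- (to exclude CK/CD4 co-staining artifacts). Both
are configurable by supplying custom rules.

The tumor compartment is the union of tumor-nest polygons per field (the
carrier for the cytokeratin-based tissue segmentation mask); a cell is
intra-tumoral iff its centroid lies inside or on the boundary of a nest
(inclusive point-in-polygon test, tolerance 1e-9 um). Tumor area plus stroma
area equals field area by construction. Nests must be pairwise disjoint; the
generator guarantees this, and user-supplied overlapping nests would
double-count tumor area.

# Quantification

Per-sample statistics pool cells and areas across fields — total count over
total compartment area — rather than averaging per-field values. This
matches count-based ratios, is robust to nearly empty fields, and is the
natural estimator for a homogeneous intensity. Zero-denominator statistics
(empty compartment, empty parent population) propagate as missing values,
never as zeros, and the exclusion is reported via a warning.

# Spatial proximity statistics

Two statistics, both Euclidean center-to-center and restricted to cell pairs
in the same field:

* **Mean nearest-neighbor distance** (`nn_mean_distance()`): for each
  reference cell, the distance to the nearest query-phenotype cell in its
  field, averaged over reference cells with at least one available query
  cell. References in fields without query cells are excluded (not assigned
  infinite distances) and counted.
* **Count-within-radius percentage** (`pct_within_radius()`): the share of
  reference cells with at least one query cell within the radius (default
  20 um), boundary inclusive — "within a 20 um radius" is read as a closed
  ball.

A cell that satisfies both the reference and query definition is never its
own neighbor. The compartment argument scopes the *reference* population;
query cells are taken from the whole field, since a stromal macrophage's
nearest CTL may legitimately sit inside an adjacent nest. No edge correction
is applied: cells near field borders have truncated neighborhoods, which
biases both statistics conservatively (longer NN distances, lower
count-within percentages) by roughly 1-3 percentage points at the default
field size and radius. This matches the behavior of the upstream per-field
imaging toolchain these statistics replicate.

The vectorized implementation is checked bit-exactly against a plain O(n^2)
brute force in the test suite, on instances up to 2,000 cells.

# Synthetic cohort generator

The study this package operationalizes is observational and deposits no
data, so validation uses a generative model expressing exactly the
quantities the analyses measure:

* **Geometry**: tumor nests are random non-overlapping discs (64-gon
  polygonized, clipped to the field) placed until a target tumor area
  fraction (default 0.40) is reached; radii are Normal(90, 15) um truncated
  at 20 um. Placement failure after 500 attempts is a generation error.
* **Cells**: each generator class (tumor, the four CD8 subsets, Treg, M1/M2
  macrophages, PD-L1+ variants) is a homogeneous Poisson process with a
  compartment-, lesion-type- and HPV-status-specific intensity; points are
  drawn by rejection within the compartment. Marker calls follow
  deterministically from the class.
* **Attraction** (off by default): a fraction rho of an attracted class is
  relocated uniformly within `r_attr` of a uniformly chosen anchor cell.
  Relocation rather than a Gibbs process keeps the rho semantics exact and
  generation single-pass.
* **Expression**: negative-binomial counts (default dispersion 0.1),
  per-gene baseline log2 means uniform on [5, 10]; housekeeping genes share
  one mean across samples, so they carry no group effect by construction; 30
  endogenous genes receive a signed log2 fold change drawn from the
  configured range (type default [1.2, 2]; the recovery experiments use
  [1.5, 2]).
* **Survival**: exponential event times with log hazard
  `log(h0) + sum(beta_k z_k)` over standardized immune features (defaults:
  intra-tumoral CD8 density beta = -0.6, stromal M2 density beta = +0.4,
  h0 = 0.012/month), administratively censored at Uniform(36, 72) months —
  a mixed-censoring pattern like a real follow-up window.

The default cohort is 39 patients (24 HPV-positive including 21 HPV16, 2
HPV33, 1 HPV18; 15 HPV-negative), each with a primary and a metastasis
lesion of 20 fields.

## Calibration of the default intensities

The shipped `default_calibration()` intensities were chosen so the
downstream count-within statistics reproduce the reported contrasts: ~30%
(HPV+) vs ~4% (HPV-) of metastasis tumor cells with a CTL within 20 um, and
~60%/40% (stroma/tumor, HPV+) vs ~20%/10% (HPV-) of M2 macrophages with a
CTL within 20 um in primary tumors. Under complete spatial randomness the
count-within expectation has the closed form `p = 1 - exp(-lambda pi r^2 /
1e6)`, which gives the initial intensity for each target percentage;
because stromal and intra-tumoral CD8 pools mix across nest boundaries and
field edges truncate neighborhoods, these initial values were refined by
Monte Carlo simulation at the study's own sample sizes (24/15 lesions x 20
fields) and then frozen. Density orderings follow the reported direction
(CD8, CD68, CD68+CD163+ higher in HPV-positive lesions at every site;
FoxP3 intensities identical between groups, hence "comparable"). The
default calibration covers the 9-color phenotypes; a parallel 6-color cell
map (CD4/CTLA-4/HLA-I) is not simulated.

## What the generator does not emulate

Cell shapes and membranes (distances are centroid-to-centroid), intensity
noise upstream of binary calls, per-sample variation in field counts (fixed
at 20), spatial heterogeneity beyond nests (no hotspots or gradients),
coupling between the spatial and expression layers beyond the shared HPV
label, and real biological correlation structure between genes. Passing
tests therefore demonstrate the correctness and calibration of the
*analysis machinery* under the stated model, not performance on real tissue.

# Expression analysis

Normalization follows the housekeeping-ratio convention: each count is
divided by the geometric mean of the sample's housekeeping counts, then
log2-transformed. Raw counts are floored at 1 beforehand so logs are always
defined; background subtraction is not modeled. Per-sample
self-normalization differs from rescaling to the cohort's mean housekeeping
level only by a per-cohort constant on the log2 scale, so fold changes,
score differences and tests are unaffected.

Differential expression is, per endogenous gene, an ordinary least-squares
regression of log2 expression on the binary HPV indicator — algebraically
the equal-variance two-sample t statistic on n - 2 degrees of freedom —
with Benjamini-Hochberg adjustment across all genes with a valid p-value
(zero-residual-variance genes are excluded from the family with a warning).
A gene is a DEG when |log2 fold change| > 1 and adjusted p < 0.05.

Signature scores are unweighted means of log2 normalized expression over
the member genes present; proprietary panel weights are not reproduced, and
the shipped signature YAML is editable configuration, not a reference list.
Signature "ratios" are score differences (log2 of the linear ratio).

# Survival analysis

Each immune variable is dichotomized at its median with values equal to the
median assigned to the low group — a deterministic, conventional tie rule.
Kaplan-Meier estimation, the log-rank (Mantel-Cox) test and univariate Cox
regression with Efron tie handling (times are months-resolution and tie
heavily) come from the `survival` package behind the module's validation
layer: DFS times of 0 are shifted to 0.01 months with a warning, monotone
partial likelihoods are flagged as non-identifiable rather than returned
silently, and screens report raw per-variable p-values (matching the
screening convention reproduced here) with a BH-adjusted column alongside.

# Group comparisons

Mann-Whitney is exact (enumeration) when the combined sample size is at
most 20 without ties, otherwise normal approximation with tie and
continuity corrections. Fisher's exact test uses the point-probability
two-sided criterion and is restricted to tables with total <= 200
(enumeration bound); larger tables should use a chi-square test. Spearman
correlation uses mid-ranks with the t-approximation p-value. Significance
stars follow the conventional levels (0.05, 0.01, 0.001, 0.0001).

A note on external consistency: two-sided Fisher p-values recomputed from
published marginal count tables do not always match printed values, which
in some cases correspond to a Pearson chi-square instead; this package
implements the enumeration definition throughout and makes no attempt to
match any specific printed table p-value.

# Numerical conventions and problem sizes

* Polygon areas via the shoelace formula; clipping via Sutherland-Hodgman;
  the disc polygonization (64 vertices) under-covers a true circle by 0.16%,
  and all areas are computed from the polygons, so the partition identity is
  exact.
* All generation is driven by a single integer seed fanned out to per-stage
  child seeds (`derive_seeds()`), making stages individually reproducible;
  identical seeds give bit-identical cohorts.
* The validation experiments use the study-scale problem sizes: 24 + 15
  lesions of 20 fields for the spatial calibration checks, 770 x 39 count
  matrices over 20 seeds for DEG recovery, 10-seed pooled null simulations
  for p-value uniformity, and 100 replicates of a 200-per-arm Cox recovery
  with true hazard ratio 2. Unit tests use smaller instances chosen to keep
  the full suite under a minute of spatial simulation.

# Known limitations

No edge-corrected spatial statistics (Ripley's K, pair correlation) and no
permutation-based spatial null models; no multivariate Cox, competing risks
or proportional-hazards diagnostics; no raw-image handling; the expression
layer models genes independently. These are deliberate scope boundaries,
not oversights.
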