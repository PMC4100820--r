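---
title: "Methods: blood-cell miRNA profiling, mass budgeting and apportionment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood-cell miRNA profiling, mass budgeting and apportionment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodmir)
```

# The problem

Most circulating miRNA is carried by blood cells, and the same miRNA can be
abundant in one hematopoietic lineage and absent in another. To say where a
microlitre of blood's content of a given miRNA comes from, three ingredients
must be combined: how much miRNA each cell type carries per cell, how many of
each cell circulate per microlitre, and what fraction of each cell type's
miRNA pool the specific miRNA represents. `bloodmir` chains those three
estimates — each with its own assay and its own failure modes — into a single
apportionment table, together with the supporting statistics (differential
expression, normalizer selection, clustering) needed to interpret it.

# Count normalization and background

Hybridization-count platforms report per-probe molecule counts per sample
lane. Lane-to-lane loading differences are removed by scaling each sample to
the geometric mean of its 100 highest endogenous counts: with
$gm_j$ the top-100 geometric mean of sample $j$, the factor is
$f_j = \overline{gm}/gm_j$ and every value in the lane (endogenous and
negative-control rows alike) is multiplied by $f_j$. Negative controls must
be scaled by the same factor because the background threshold is subtracted
from *normalized* values; thresholding raw controls against normalized
expression would mix scales.

Notes on the exact conventions, which matter for reproducibility:

* **Top-100 selection** is per sample on raw endogenous counts; ties at rank
  100 are broken by probe-id lexicographic order so the selected set is
  deterministic.
* **The reference level** $\overline{gm}$ is the arithmetic mean of the
  per-sample geometric means (the vendor's lane-normalization convention).
  This makes one sample's normalized values depend weakly on which other
  samples are present; passing a fixed `target` to
  `top100_geomean_normalize()` removes that coupling when exact
  batch-independence is needed. Relative quantities (relative abundance,
  shares, CV ranking, clustering) are invariant either way.
* **Background** is `mean + 2 SD` of the sample's normalized negative
  controls, with the sample (n−1) standard deviation; the platform does not
  fix the denominator convention, so it is stated here and tested.
* **Erythrocyte override.** Erythrocyte preparations can show anomalously low
  negative-control values; left alone, their threshold would admit hundreds
  of biologically irrelevant near-zero probes. The override replaces each
  flagged sample's threshold with the mean of the own-sample thresholds of
  all samples of the other cell types. "Similar to the other lineages" admits
  several readings (mean, median, max); the mean of the other samples'
  thresholds is the simplest estimator that uses all available information,
  and the rule is configurable (`override =`) and flagged per sample in the
  output.
* **Subtract vs censor.** Whether background should be subtracted from values
  or merely used to zero sub-threshold values is genuinely ambiguous in this
  workflow's provenance; both are provided (`mode = "subtract"` is the
  default, `"censor"` keeps supra-threshold values unscaled). "Expressed
  above background" means a strictly positive result in either mode.

# Relative abundance, detection and classes

Relative abundance divides each probe's processed value by the sample total,
so per-sample fractions sum to 1 (asserted to 1e−9). Cell-type averages are
arithmetic means over member samples; the apportionment deliberately uses
these averages rather than per-donor values, treating the five donors as
replicates of a common lineage profile.

"Detected in a cell type" is defined as a positive cell-type *mean* processed
value (`rule = "mean"`); the alternative `"any-sample"` rule is provided
because summary counts of detected miRNAs are sensitive to this choice and
the convention is rarely stated in published pipelines. Expression classes
use fixed count thresholds on the processed scale: `low` < 10 counts,
`high` > 5,000 counts, applied to the cell-type mean.

# Mass budgeting

Electropherograms from size-resolving capillary electrophoresis give mass
fractions by area under the fluorescence-vs-size curve. `auc_fraction()` uses
trapezoidal integration with linear interpolation at the cutoff; the miRNA
fraction of total RNA is the product of two such fractions (area < 150 nt of
the total-RNA assay × area < 40 nt of the small-RNA assay). The unit chain is
fixed once: `ng × 10⁶ / cells` = fg/cell; `fg/cell × cells/µl × 10⁻³` =
pg/µl. Size cutoffs (150 nt, 40 nt) are arguments with those defaults.

For each probe the apportionment weight of cell type $c$ is
$w_c = (\text{miRNA fg/cell})_c \times (\text{cells/µl})_c$ and the share is
$100\, a_c w_c / \sum_{c'} a_{c'} w_{c'}$. Shares are scale-invariant in any
common rescaling of the weights, each row sums to exactly 100% in floating
point (asserted to 1e−6), and probes with zero total mass are flagged rather
than divided by zero. Rounding to whole percent happens only at
serialization, because rounded rows legitimately sum to 99–101%.

The bundled cell-prep defaults (`generate_cell_records()`) encode reference
per-cell masses for healthy adult blood; the cells-per-µl values are derived
from those masses and per-volume contributions (pg/µl ÷ fg/cell × 1000) and
land at physiological CBC values (≈ 3.4 × 10⁵ platelets, 1.1 × 10³ T-cells,
2.0 × 10² B-cells, 4.9 × 10³ granulocytes, 4.6 × 10⁶ erythrocytes per µl).

# Differential expression

Lineages have grossly unequal variances on the count scale, so the omnibus
test is Welch's unequal-variance one-way ANOVA, computed from the Welch
(1951) formula with Welch–Satterthwaite denominator df. Tests run by default
on `log2(x + 1)` processed values — the transform is configurable
(`scale = "linear"`) because the choice is not dictated by the workflow's
provenance, but count noise is closer to log-normal and the post-hoc tests'
pooled-variance assumption is far more defensible on the log scale.
Multiplicity is controlled by Benjamini–Hochberg at q < 0.05.

Degenerate inputs are resolved deterministically rather than erroring:
all-constant-and-equal groups give F = 0, p = 1; a constant group among
varying groups has its variance floored at 1e−12 of the largest within-group
variance (an effectively infinite-precision group), and zero-variance-everywhere
probes are reported with p = 1.

Post-hoc testing pairs the Welch omnibus with classical pooled-variance
studentized-range procedures: Tukey when the probe is present in all five
cell types, Student–Newman–Keuls when it is absent (all samples zero after
background correction) in at least one. Pooling variances after a
heteroscedasticity-robust omnibus is statistically impure, but this pairing
is the established convention in the commercial pipelines this package
mirrors, so fidelity wins over purity; the family-wise post-hoc alpha is
fixed at 0.05 per probe. "Absent" needed a definition and gets the strictest
one (every sample exactly zero). A lineage's DE list contains probes that are
globally significant *and* post-hoc separated from all four other lineages.
SNK uses the classical stepwise protection rule: spans that test
non-significant block every nested comparison; homogeneous subsets are
maximal runs of ordered means containing no significant pair.

# Normalizer stability

The model-based stability criterion follows the Andersen variance-decomposition
approach on log2 values. Values are first sample-centered (subtracting each
sample's mean across probes), which removes any per-sample additive constant —
the analogue of global loading differences. Per probe and group the method
estimates an inter-group deviation $d_{gi}$ and an intra-group variance
$s^2_{gi}$; the stability value is
$\frac{1}{G}\sum_g \left(|\tilde d_{gi}| + \sqrt{s^2_{gi}/n_g}\right)$,
lower being more stable. Two numerical details:

* the observed within-group variance of centered values is biased by the
  centering term; with $k$ probes,
  $E[s^2_{obs,i}] = \sigma^2_i(1 - 2/k) + S/k^2$ where $S = \sum_{i'} \sigma^2_{i'}$,
  which is inverted exactly and floored at zero;
* $d_{gi}$ is shrunk by the empirical-Bayes factor
  $\hat\gamma^2/(\hat\gamma^2 + s^2_{gi}/n_g)$, with $\hat\gamma^2$ the
  across-probe mean square of the raw deviations (df $(k-1)(G-1)$) net of
  their sampling variance, floored at zero.

The CV criterion is the plain sample SD/mean on linear normalized values.
Probes absent in any lineage are excluded from candidacy — a normalizer must
be expressed everywhere it will be used. The model-based input scale is
log2(x + 1); CV is computed on the linear scale, where it has its usual
meaning. One documented oddity inherited from this workflow's provenance: the
selected blood-cell normalizer is referred to as both *miR-30c-5p* and
*miR-30c-3p* in different places of the original report; the discrepancy is
preserved here verbatim rather than silently resolved.

# Clustering

Samples are clustered on 1 − Pearson correlation with complete linkage
(`stats::hclust`), whose merge heights are provably non-decreasing. The
default input panel is the union of each lineage's top-20 most abundant
miRNAs on log2(x + 1) values — the abundant-probe convention keeps the
distance dominated by miRNAs that actually carry lineage signal. Constant
sample vectors are rejected by name (their correlation is undefined). The
heatmap transform is `log2((x + 1)/(rowmean + 1))` per probe row; the row
mean was chosen as the log-ratio reference because the "average" reference of
typical heatmap viewers is otherwise unspecified, and all-zero rows map to
all-zero output.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is validated. Defaults model a paired
design of 5 donors × 5 purified cell types, 623 endogenous probes and 6
negative controls.

* **Counts** are `round(2^(baseline + lineage effect + donor effect +
  residual))`. Lognormal-then-round was chosen over negative binomial
  because the platform reports deterministic molecule counts and all
  downstream statistics operate on normalized continuous values; the
  log-scale decomposition is exactly the structure those statistics assume.
* **Baselines** are N(5, 2.5²) log2 counts, spreading probes over ~5 orders
  of magnitude, matching the dynamic range of real blood-cell profiles.
* **Lineage structure**: 15% of probes receive independent per-cell-type
  offsets with SD 1.5 log2 units. These values were fixed once as a
  realistic degree of cross-lineage structure — strong enough that abundant
  probes separate the five lineages in unsupervised clustering, sparse
  enough that most probes are exchangeable; under the default noise they
  yield on the order of 90 of 623 probes differentially expressed, the same
  order as real cross-lineage blood comparisons.
* **Noise**: donor SD 0.25 (per probe × donor, shared across that donor's
  cell types to emulate paired sampling) and residual SD 0.25 log2 units.
* **Planted truth**: lineage-specific probes (default: two per lineage,
  8-fold), stable normalizer probes (zero lineage effect, noise damped to
  0.2×, baseline fixed at log2 mean + 3 so they sit well clear of
  background), optional structurally absent probes, and share-planted probes
  whose lineage means invert the apportionment arithmetic so a target share
  pattern (e.g. 0/84/10/5/1%) is recoverable end to end.
* **Negative controls** are truncated-normal at zero (mean 4, SD 2 counts;
  free parameters, since raw background magnitudes are platform-specific),
  with the erythrocyte mean lowered to 0.8 to reproduce the situation that
  motivates the threshold override.
* **Electropherograms** are two-component Gaussian peak mixtures whose peak
  positions sit several SD from the 150/40 nt cutoffs, so target area
  fractions are realized within 1% despite 2% multiplicative intensity
  noise.

What the generator does **not** emulate: probe cross-hybridization,
codeset batch effects, ligation bias, count overdispersion beyond lognormal,
donor-by-lineage interactions, or extracellular/microvesicle miRNA pools.
Passing tests on synthetic data therefore demonstrate correctness of the
computations under the stated model, not robustness to platform artifacts.

# Problem sizes and determinism

Every generator accepts a seed and restores the caller's RNG state; the same
seed gives byte-identical output. The test suite runs the full 623-probe,
25-sample design where the claim depends on study scale (clustering, share
recovery, detection counts), and smaller panels (10–200 probes) where the
claim is algebraic; moment-recovery checks use 60 donors at 40 probes, and
null-calibration checks use 1,000 exchangeable probes. These sizes keep the
whole suite in the seconds-to-a-minute range while leaving each statistical
check adequately powered.

# Known limitations

* The apportionment inherits all biases of its inputs: purification losses,
  extraction-efficiency differences between cell types, and reference (not
  donor-matched) lymphocyte concentrations propagate directly into shares.
* The background-subtraction constant shifts low counts nonlinearly on the
  log scale; probes near threshold are the least reliable everywhere in the
  pipeline.
* v1/v2 codeset reconciliation by suffix-stripped probe-name identity is an
  assumption; renamed probes between codeset versions would need an explicit
  alias table.
* GEO ingestion reads local series-matrix files only and infers probe
  classes from id prefixes; the reader does not fetch from the network.
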