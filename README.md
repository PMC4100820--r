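# bloodmir

Circulating miRNAs are promising disease biomarkers, but interpreting a blood
miRNA level requires knowing *which cells it comes from*. `bloodmir` implements
the quantitative side of that question for the five major peripheral-blood
hematopoietic populations — platelets, T-cells, B-cells, granulocytes and
erythrocytes — from hybridization-count (nCounter-style) miRNA profiles of
purified cell preparations. It is aimed at transcriptomics analysts who want a
tested, scriptable reimplementation of this cross-lineage mass-budgeting
workflow, with a synthetic-data generator so every stage can be validated
against known ground truth.

## What it computes

**Normalization and background.** Counts are scaled per sample to the
geometric mean of the 100 highest-expressed endogenous probes
(factor&nbsp;<i>f<sub>j</sub></i> = mean<sub>j′</sub>(gm<sub>j′</sub>) /
gm<sub>j</sub>), then a per-sample background threshold — mean of the
negative-control probes + 2&nbsp;SD — is subtracted with a floor at zero.
Erythrocyte samples, whose negative controls run anomalously low, instead use
the mean of the other lineages' thresholds.

**Mass budgeting.** Per-cell total RNA is `ng × 10⁶ / cells` (fg/cell). The
miRNA fraction of total RNA is the product of two electropherogram
area-under-curve fractions: area &lt; 150 nt of the total-RNA trace × area
&lt; 40 nt of the small-RNA trace. Each lineage's blood contribution is
`fg/cell × cells/µl × 10⁻³` (pg/µl).

**Apportionment.** A miRNA's blood content is split across lineages by
`share_c = 100 · a_c w_c / Σ a_c′ w_c′` with `a_c` the cell-type-average
relative abundance and `w_c = (miRNA fg/cell)_c × (cells/µl)_c`. Every row
sums to 100% before display rounding.

**Statistics.** Differential expression across lineages uses Welch's
unequal-variance one-way ANOVA with Benjamini–Hochberg FDR control
(q &lt; 0.05), followed by Tukey (probe present in all lineages) or
Student–Newman–Keuls (probe absent somewhere) studentized-range post-hoc
tests. Reference-normalizer candidates are ranked by an Andersen-style
model-based stability value (inter-group deviation + intra-group variance,
lower is better) and by coefficient of variation. Samples are clustered by
complete linkage on 1 − Pearson correlation over the union of each lineage's
top-20 most abundant miRNAs.

## Worked example

```r
library(bloodmir)

ds     <- generate_count_dataset(sim_config(seed = 1))   # 623 probes, 5 donors x 5 lineages
proc   <- process_counts(ds$experiment)                  # normalize + background
budget <- build_mass_budget(generate_cell_records())     # per-cell and per-volume masses
budget
#>     cell_type total_rna_fg_per_cell mirna_fraction_of_total mirna_fg_per_cell
#> 1    platelet                  2.20                0.022727              0.05
#> 2      T-cell               2187.97                0.001499              3.28
#> 3      B-cell               1360.34                0.002323              3.16
#> 4 granulocyte                646.30                0.015829             10.23
#> 5 erythrocyte                  0.57                0.070175              0.04
#>   cells_per_ul mirna_pg_per_ul_blood rank
#> 1     338000.0                 16.90    3
#> 2       1082.3                  3.55    4
#> 3        202.5                  0.64    5
#> 4       4911.0                 50.24    2
#> 5    4600000.0                184.00    1
```

Nucleated cells carry the most RNA per cell (T-cells 1.61× B-cells, B-cells
2.10× granulocytes), but per microlitre of blood the miRNA mass ranking is
erythrocyte &gt; granulocyte &gt; platelet &gt; T-cell &gt; B-cell — sheer
cell numbers dominate per-cell content.

```r
shares <- apportion_blood_shares(relative_abundance(proc), budget)
shares[shares$probe == "syn-miR-de-009", ]   # an erythrocyte-planted miRNA
#>          probe platelet T-cell B-cell granulocyte erythrocyte total_pg_per_ul
#> syn-miR-de-009      0.8    0.2      0         3.3        95.7           0.429

de_by_cell_type(proc)
#> de_result: 87/623 probes DE at q < 0.05 (log2p1 scale)
#>   platelet     26 lineage-specific probes
#>   ...

head(stability_ranking(proc)$top, 3)
#>   rank        normfinder                cv
#> 1    1 syn-miR-stable-01 syn-miR-stable-03
#> 2    2 syn-miR-stable-03 syn-miR-stable-01
#> 3    3 syn-miR-stable-02 syn-miR-stable-02
```

The planted erythrocyte-specific probe is correctly apportioned ~96% to
erythrocytes, the planted lineage-specific probes drive the DE lists, and the
three planted zero-effect low-dispersion normalizers top both stability
rankings.

A command-line front end over the same functions lives at
`inst/cli/bloodmir.R` (`simulate`, `normalize`, `abundance`, `budget`, `de`,
`stability`, `cluster`, `convert`).

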