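---
title: "Cross-modal imputation of marker-positive cell counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal imputation of marker-positive cell counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasxref)
```

## The problem

Whole-brain single-cell atlases are organised around microdissected
regions, and those regions rarely coincide with the anatomical structures a
study cares about. The olfactory-area ("OLF") dissection, for instance, is
substantially broader than the main olfactory bulb (MOB), accessory
olfactory bulb (AOB) and anterior olfactory nucleus (AON). So "how many
cells in the MOB express gene X, and of what neuronal class?" cannot be
answered from the scRNA-seq atlas alone. Imaging-based spatial
transcriptomics (MERFISH) has the opposite limitation: every cell carries a
taxonomy cluster label and a CCFv3 structure acronym, but the measured gene
panel may not include the marker of interest, or may detect it poorly.

`atlasxref` combines the two modalities. The scRNA-seq data estimate, per
taxonomy cluster, how often cells of that cluster express the marker; the
spatial data say how many cells of each cluster sit in each structure; the
product imputes the expected number of marker-positive cells per structure.

## The model

Let cells of cluster $k$ in the region-filtered scRNA-seq table number
$n_k$, of which $x_k$ have raw marker count $\ge \tau$. The marker-positive
prevalence is the plug-in binomial estimate

$$\hat f_k = x_k / n_k,$$

with an equal-tailed Jeffreys interval from the
$\mathrm{Beta}(x_k + \tfrac12,\, n_k - x_k + \tfrac12)$ quantiles. The
interval is an addition of this package (the underlying cross-reference
procedure reports only point fractions); it exists so that simulation
studies can check calibration. We use the conventional boundary
modification — the lower limit is set to 0 when $x_k = 0$ and the upper
limit to 1 when $x_k = n_k$ — so the interval always contains $\hat f_k$,
at the cost of making those two limits one-sided.

A cluster is *relevant* when $x_k \ge 1$: the only criterion carried into
the spatial stage is prior detection of the marker in that cluster
(`min_npos` makes the cut-off configurable). With $n_{s,k}$ the number of
retained spatial cells of relevant cluster $k$ in target structure $s$, the
imputed expected marker-positive count is

$$\hat E[s] = \sum_k n_{s,k} \, \hat f_k,
\qquad
\hat E[s,c] = \sum_{k:\, \mathrm{class}(k) = c} n_{s,k} \, \hat f_k,$$

and the per-structure composition is $100\,\hat E[s,c]/\hat E[s]$. Since
each $\hat f_k \in [0,1]$, $\hat E[s]$ never exceeds the tabulated cell
count $n_s$, and the class-wise terms sum to $\hat E[s]$ exactly (we assert
this to $10^{-9}$ relative in tests). When the spatial and single-cell
draws are independent, $\hat E[s]$ is unbiased for the true expected count
$\sum_k N_s \theta_{s,k} p_k$, which the replication study below verifies.

Two deliberate interpretation choices:

* **Denominator scope.** Fractions are computed within the region-filtered
  table, not the whole dataset, so the detection conditions of numerator
  and denominator match. `whole_table_denominator = TRUE` switches to
  dataset-wide denominators for sensitivity analysis.
* **Composition over cells, not clusters.** The positive-population
  breakdown weights each positive *cell* equally; a cluster-weighted
  summary would not reproduce a headline count of positive cells.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tau` | 1 | raw-count positivity threshold (counts; 1 = "non-zero expression") |
| `region` | `"OLF"` | dissection region the single-cell table is restricted to |
| `structures` | `MOB, AOB, AON` | target acronyms after roll-up |
| `sections` | all | spatial section ids retained (a real-data profile would pin the five sections used for the olfactory structures) |
| `conf_level` | 0.95 | Jeffreys interval level (0.99 in the calibration study) |
| `min_npos` | 1 | positives required for a cluster to be relevant |
| `strict` | `TRUE` | unknown cluster ids are errors rather than `unassigned` |

Thresholding is always on **raw counts**: normalisation can only change
zero-ness pathologically, and the positivity definition is a statement
about detected molecules, not about relative expression.

## Structure roll-up

Anatomical annotations arrive at layer or substructure resolution
(`MOB-gl` and the like) while the analysis wants whole structures. The
default `structure_map()` sends any acronym with a target as its prefix to
that target (longest match wins, so nested target sets resolve
deterministically), maps each target to itself (the roll-up is idempotent),
and leaves everything else unmapped — those rows are excluded and counted,
never silently kept. A real-data adapter should replace the prefix
heuristic with the atlas's own parcellation-term table via the `extra`
argument, since acronym prefixes are a convention, not an ontology.

## Strictness and failure modes

Joins between tables never silently drop or invent information. In strict
mode (the default, intended for real exports) a cluster id missing from the
taxonomy, or observed in the spatial table but absent from the prevalence
table, aborts the run; in lenient mode (synthetic smoke tests) those rows
are mapped to `unassigned` or excluded with a warning. Imputing $f = 0$ for
a cluster the single-cell data never saw is forbidden in both modes.
Errors carry condition classes — `atlasxref_validation_error` for schema
and consistency violations, `atlasxref_empty_error` for legitimate inputs
that leave a stage with nothing to do (no cells in the region, no positive
cell, no relevant cluster) — so callers and tests can tell the two apart
without parsing messages.

## The synthetic generator

`sim_spec()` describes a paired atlas: per cluster a true positivity
probability $p_k$ and a single-cell sample size; per structure a cell count
$N_s$ and mixing weights $\theta_{s,\cdot}$ over clusters; section
assignment weights; one seed. `generate_sc()` draws each cell positive with
probability $p_k$ and gives positive cells a count of $1 +
\mathrm{Poisson}(\lambda)$ — the analysis only consumes zero versus
non-zero at $\tau = 1$, but the extra mass keeps $\tau > 1$ experiments
meaningful. `generate_spatial()` draws each structure's cells from
$\theta_{s,\cdot}$. The two tables use independent RNG substreams derived
from the one seed, so resizing one never perturbs the other, and identical
spec plus seed yields byte-identical files.

The generator emulates exactly the statistical structure the estimator
assumes: cluster-conditional detection and structure-conditional cluster
composition. It deliberately does **not** emulate full transcriptomes,
batch or section effects, doublets, segmentation errors, spatial
autocorrelation within structures, or section damage and misalignment.
Passing recovery tests therefore show the estimator is correct and
calibrated *under its own assumptions*; they cannot show robustness to the
annotation and registration artefacts of real spatial data.

`default_sim_spec()` is the fixture used throughout the tests and scripts:
three clusters (glutamatergic $p = 0.5$, GABAergic $p = 0.2$, dopaminergic
$p = 0$) over MOB, AOB, AON, with the AOB purely glutamatergic. At its
default small sizes its closed-form truth matches the worked example
(expected positives 7.0 in MOB, 2.0 in AOB):

```{r toy}
res <- run_pipeline(toy_sc_cells(), toy_taxonomy(), toy_spatial_cells())
res$prevalence[, 1:5]
res$imputation$structures
```

## Calibration and problem sizes

The replication study (`analysis/04_recovery.R`, and the second half of
`scripts/acceptance.R`) runs 100 seeded replicates at 2,000 single cells
per cluster and 3,500 spatial cells (2,000 MOB / 500 AOB / 1,000 AON).
These sizes put the binomial standard error of $\hat f_k$ near 0.01 —
comparable to a well-powered atlas dissection — while the whole study runs
in seconds. Two properties are checked: the 99% Jeffreys interval covers
the true $p_k$ in at least 97 of 100 replicates per cluster, and the mean
of $\hat E[s] - E_{\text{true}}[s]$ lies within three standard errors of
zero for every structure.

## Numerical choices and edge cases

* Counting is exact integer arithmetic; only fractions and expectations are
  floating point, with a $10^{-9}$ relative tolerance asserted on
  additivity.
* Clusters are reported in lexicographic `cluster_id` order; structures in
  lexicographic acronym order. Percentages are computed at full precision
  and rounded only for display.
* A structure whose expected count is zero gets `NA` composition
  percentages (a dash in the text report) rather than 0/0.
* Empty region filter, all-zero marker counts, and an all-irrelevant
  spatial table each raise a classed empty-result error rather than
  returning a degenerate table.
* Fractions are serialized to TSV with 15 significant digits so that the
  writer–reader composition is the identity.

## Limitations

* The core consumes the documented TSV schema only. Exports from an
  HDF5-backed atlas release must be converted upstream (any h5ad-capable
  tool can emit the four required columns per table); the package does not
  read HDF5 itself, and the atlas release used must be pinned by whoever
  exports.
* One marker per run; no co-expression logic, no differential expression.
* Coordinates are carried through untouched; there is no spatial smoothing,
  neighbourhood analysis, or per-layer breakdown within a target structure.
* The imputation propagates only the sampling uncertainty of $\hat f_k$
  that the Jeffreys intervals quantify per cluster; no interval is reported
  for $\hat E[s]$ itself.
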