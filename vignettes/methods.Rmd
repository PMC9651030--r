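---
title: "Methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette records the statistical model behind each stage of
`xodosage`, the defaults and why they were chosen, and the numerical
decisions a reader would otherwise have to reverse-engineer from the
code. Code chunks are illustrative and not evaluated.

## 1. The synthetic study

The generator is not a toy: its defaults define the reference study
conditions under which the package's claims (X identification bands,
regime recovery rates, FDR control, power) are stated and tested.

**Genome.** `n_autosomes = 14` plus one X, matching a karyotype of
2n = 30/29 (XX/XO). Each chromosome carries `n_genes_per_chrom = 2000`
non-overlapping genes tiled at `gene_spacing = 6000` bp (chromosome
length 12 Mb), in the ballpark of a ~30,000-gene annotation and — at the
default `window_size = 1e5` — giving 120 coverage windows per
chromosome. Gene spans and exonic lengths are randomized per gene.

The gene count per chromosome matters for the dosage call: the X:A ratio
is a ratio of two medians of roughly log-normal FPKMs with
`baseline_sdlog = 1.5`, so the standard error of each log-median is
about `1.5 * sqrt(pi / (2 n))`. At n = 2000 X-linked genes the male X:A
ratio fluctuates by a few percent, comfortably inside the ±0.15 decision
band; with only a few hundred genes it would not.

**Coverage.** Per-window depths are Poisson: females at
`depth_female = 100` on every chromosome, males at the same rate on
autosomes and at half rate on the X (one copy instead of two). Equal
per-copy sequencing depth in both sexes is by construction, which is why
the acceptance targets are computed without library-size rescaling.

**Expression.** Per-gene baseline FPKM is log-normal
(`meanlog = 3`, `sdlog = 1.5`). Counts are negative binomial with
dispersion `0.04` (BCV 0.2, a standard figure for genetically identical
lines) around the mean implied by the FPKM identity
`mu = FPKM * length_kb * libsize / 1e6` with `libsize = 5e6`. The
compensation regime sets the male X multiplier: 1 under
`complete_compensation`, 0.5 under `no_compensation`, with females
halved instead under `female_downregulation`. 5% of genes per direction
are sex-biased at `bias_fold = 8`; `bias_female_on_x` optionally
concentrates female-biased genes on the X to create a recoverable
enrichment signal. Truth labels for every gene are emitted alongside the
counts.

The log-normal baseline is a simplification (real FPKM distributions
have a heavier zero/low tail); it is the main axis along which the
generator is idealized, and the robustness of the median-based
statistics to it is exactly what the regime-recovery tests exercise.

**Reproducibility.** All randomness flows through named streams derived
from `(seed, stream-name)`, so genome, coverage and expression draws are
independently reproducible and adding a stage never perturbs another
stage's draws.

## 2. X identification

Windowed M:F depth ratios, with windows dropped when female depth falls
below `min_depth = 5` (ratio denominators become unstable) or male depth
is zero. When the two libraries were sequenced to different total depths
(`normalize_libsize = TRUE`), provisional ratios are divided by their
genome-wide median — autosomes dominate any realistic genome, so this
centres the autosomal ratio at 1 without needing the classification
first.

Classification is deliberately simple: the per-chromosome **median**
window ratio against two disjoint bands, X in `[0.35, 0.65]` and
autosome in `[0.8, 1.2]`, `unassigned` otherwise or when fewer than
`min_windows = 5` windows survive. Medians, not means: single
high-coverage repeat windows should not move a chromosome between bands.

LOESS smoothing (degree-1 local regression, tricube weights over the
`span = 0.3` nearest fraction of windows, fitted per chromosome so
smoothing never crosses a boundary) is attached for visualization only;
the classifier always works on raw per-window ratios. The local fit uses
the closed-form weighted-least-squares intercept at the centred
abscissa, falling back to the weighted mean when the neighbourhood is
degenerate.

## 3. Normalization

TMM is implemented in the package (and cross-checked against
`edgeR::calcNormFactors` in the tests, not delegated to it): reference =
the sample whose upper-quartile fraction is closest to the mean; M and A
values from genes positive in both samples; double trim of 30% on M and
5% on A via rank bounds; precision-weighted mean of M with delta-method
variance weights; factors rescaled to have product 1. FPKM uses
TMM-scaled effective library sizes. Replicates are averaged on the FPKM
scale per tissue and sex.

The expression filter follows the rule "FPKM < 1 in males **and**
females" (`both_below`, the default): a gene is dropped only when both
sexes are below threshold, so sex-limited genes survive. The stricter
`either_below` variant is selectable.

## 4. Dosage statistics

Two deliberately different routes, because they fail differently:

- **X:A per sex** — ratio of the median X FPKM to the median autosomal
  FPKM. Sensitive to composition: a handful of strongly female-biased
  genes on the X inflates the female X:A while leaving the male one
  alone (visible in the demo, where female X:A exceeds 1 although the
  per-gene statistic sits at 1).
- **Per-gene F:M ratios** — median of `mean_F / mean_M` per gene
  (denominators floored at `floor = 0.01` FPKM), X versus autosomes,
  with a two-sided Wilcoxon rank-sum test between the two ratio
  distributions. The median of per-gene ratios is robust to the biased
  minority that moves the ratio-of-medians.

The status call combines both with bands `delta = epsilon = 0.15`
(generous relative to the measured standard errors at the default gene
count, tight enough to separate ratios of 1 from 0.5 or 2):

| status | F:M on X | male X:A |
|---|---|---|
| `complete_with_balance` | within `1 ± delta` | within `1 ± epsilon` |
| `complete_unbalanced`   | within `1 ± delta` | outside |
| `absent`                | `>= 2 - delta` | — |
| `partial`               | anything else | — |

The Wilcoxon wrapper uses the exact distribution when the smaller group
has at most 8 tie-free observations and the normal approximation with
continuity correction otherwise, and is validated against a full
enumeration oracle in the tests.

## 5. Sex-biased genes

**Filter.** CPM > 1 (strict) in every replicate of at least one sex for
replicated designs. For unreplicated designs, CPM > 1 in at least one of
the two samples — requiring both would silently discard exactly the
sex-limited genes the analysis is about.

**Dispersion.** Unreplicated: fixed at `bcv^2 = 0.04` for every gene.
Replicated: method-of-moments `(v - m) / m^2` on depth-scaled counts
within each sex, pooled across sexes by residual degrees of freedom,
shrunk toward the across-gene median with prior weight `prior_n = 10`
and floored at `1e-4`. This is a transparent stand-in for empirical-
Bayes tagwise machinery, not a re-derivation of it; the shrinkage
constant is a policy choice.

**Test.** Female-over-male orientation throughout.

- `lrt` (default for replicated designs): NB means per group fitted by a
  vectorized Newton iteration on `beta = log m` with library-size
  offsets at fixed dispersion, likelihood-ratio statistic against the
  pooled fit referred to chi-squared(1). Matches `edgeR::glmFit` /
  `glmLRT` at the same fixed dispersion to ~1e-4 in the tests.
- `exact` (default for unreplicated designs): counts are quantile-mapped
  (mid-P) onto the geometric-mean library size under the fitted null,
  group sums use the NB closure (a sum of k iid NB(mu, phi) is
  NB(k mu, phi/k)), and the two-sided p sums all conditional outcomes no
  more probable than the observed one. As `phi -> 0` this collapses to
  the conditional binomial, giving the exact 2/1024 check on counts
  (0, 10); an independent convolution-based oracle covers `phi > 0`.

log2 fold changes use a prior count of 0.5 scaled by relative library
size. Calls use strict thresholds `|logFC| > 2` and BH `FDR < 0.05`
(logFC exactly 2 is unbiased).

**Enrichment.** 2×2 Fisher exact test, rows (biased, unbiased) ×
columns (X, autosome), per direction; genes biased in the other
direction or on unassigned chromosomes are excluded. Odds ratio is the
cross-product `ad/bc` with `Inf`/`NA` reported symbolically and OR > 1
meaning over-representation on the X; an empty margin returns a missing
result with a warning rather than an error, since a tissue with no
biased genes is a legitimate outcome.

## 6. Pipeline

One YAML/R configuration with per-stage blocks; unknown keys are
rejected by their dotted path. Each stage writes its tables as TSV and
the final `report.json` is assembled purely from those on-disk TSVs, so
every number in the report is traceable to a stage artifact and
`--from-stage` resumption cannot diverge from a fresh run's structure.
Identical configurations reproduce `report.json` byte for byte. The
per-tissue test design (replicated/unreplicated) is auto-detected from
the replicate structure and can be overridden per tissue.

```{r}
library(xodosage)
cfg <- pipeline_config("demo_run/demo.yaml",
                       sexchrom = list(min_depth = 10))
run_pipeline(cfg, from_stage = "sexchrom")
```

## 7. Problem sizes

Unit tests run on reduced genomes (60–400 genes per chromosome) where
the assertions are scale-free (oracle equalities, invariances,
validation). Claims that *depend* on size — decision-band reliability,
regime recovery across 20 seeds, FDR/power — are tested at the default
study conditions in `test-acceptance.R`. Full-scale runs (2000 genes per
chromosome, 4 samples) take a few seconds each.
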