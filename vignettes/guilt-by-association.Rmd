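---
title: "Guilt-by-association mining of proteome abundance matrices: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guilt-by-association mining of proteome abundance matrices: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbamine)
```

## The model

Guilt-by-association (GBA) assumes that proteins acting in a common
pathway co-vary in abundance across a large, heterogeneous cohort of cell
lines or patient samples. gbamine operationalizes this with rank
correlation: for a proteins-by-samples intensity matrix it computes the
full Spearman correlation matrix and, for any query protein, returns all
proteins ordered by descending correlation. The method is deliberately
cutoff-free — no per-correlation significance threshold is imposed, because
in a cohort of many hundreds of samples even modest correlations can be
informative when they place a protein near the top of thousands of
candidates. The rank, not the correlation magnitude, is the interpretable
output.

The supporting statistics answer a different question — *does this dataset
carry a GBA signal at all?* Two complementary checks are provided:

* **Term medians.** For each annotation term (a set of proteins sharing a
  functional label), the median of all pairwise correlations between member
  proteins present in the matrix. If function drives co-variation, the
  distribution of these per-term medians sits to the right of the median of
  all correlations in the dataset.
* **Pair-set enrichment.** The correlation distribution of a curated set of
  functionally linked pairs (e.g. synthetic-lethal partners) against the
  same background; the summary is the shift of medians.

## Missing values and the undefined-correlation policy

Label-free proteomics matrices are sparse, and missingness is informative:
low-abundance proteins fall below the detection limit more often. gbamine
imputes **exactly zero** for every missing cell before correlating. Under a
rank transform this is a mild assumption — it says only that an undetected
protein is less abundant than any detected value — and it lets sparsely
detected proteins participate in the analysis at all. Two consequences are
handled explicitly:

* Zero imputation creates large blocks of tied values, so ranks use the
  average-tie (mid-rank) convention throughout.
* A protein missing (or otherwise constant) in *every* sample has zero rank
  variance and no defined correlation. Such entries are reported as 0 — so
  they are neutral in rankings — but additionally flagged in a symmetric
  logical `undefined_mask`, preserving the distinction between "estimated
  to be 0" and "not estimable". The diagonal is defined as exactly 1
  regardless, so a query always heads its own ranked list.

The background distribution for the validation statistics includes
undefined-set-to-zero entries by default (it is the distribution of "all
correlations in the dataset" as consumed downstream); callers who want the
estimable background only can set `exclude_undefined = TRUE`.

## Numerical choices

* The matrix is computed by a rank-once, standardized cross-product path:
  ranks are computed once per protein, centred, scaled to unit sum of
  squares, and multiplied (`tcrossprod`). This is algebraically identical
  to per-pair rank-then-Pearson (unit tests enforce agreement within
  1e-10; the no-ties closed form `1 − 6Σd²/(n(n²−1))` is matched to 1e-12)
  and is what makes a 15,000-protein × 1,200-sample atlas feasible: the
  cross-product is a single level-3 BLAS call, and the implementation
  re-binds intermediates so peak memory stays near the ~1.8 GB of the
  result itself.
* The BLAS symmetric-rank-k update returns an exactly symmetric matrix;
  entries are clamped into [−1, 1] against floating-point overshoot, and
  the diagonal is set to exactly 1.
* Ranked lists break correlation ties lexicographically by partner id, so
  output is deterministic; the query is pinned to rank 1 even if a partner
  ties at rho = 1. Reported positions therefore include the query; the
  `include_query = FALSE` flag gives partner-only ranks (the conventions
  differ by exactly 1).
* Term medians exclude pairs with correlation **exactly** 1 — duplicate
  abundance profiles (e.g. shared peptide evidence) carry no association
  information. The literal `== 1` reading is the default; the
  `exclusion = "near_one"` option widens this to `|rho| ≥ 1 − 1e-12` for
  floating-point duplicates. Each unordered pair contributes once; the
  diagonal never enters. Terms are not size-filtered beyond needing ≥ 2
  present members — fewer yields an absent (NA) median rather than an
  error.
* Quartile summaries (correlation ranges, abundance ranges) use the
  inclusive linear-interpolation convention (`stats::quantile` type 7),
  stated because quartile conventions differ across tools. Abundance
  summaries are computed after zero imputation, so a protein detected in
  few samples has median and quartiles driven to 0, with the zero/missing
  count reported alongside.

## The differential stage

The two-condition replicate analysis (the volcano computation) works on
log2 intensities: `log2fc = mean(log2 B) − mean(log2 A)`, a two-sided
two-sample t test per protein, and Benjamini–Hochberg adjustment across all
tested proteins. Group-level aggregation for a protein complex is
`2^mean(member log2fc)` — the geometric mean of member folds, the natural
aggregate for multiplicative changes.

The default test pools variances (`test = "student"`). This was a genuinely
open choice and we examined it by simulation: at n = 4 replicates per
condition — the typical replicated-proteome design — Welch's unequal-variance
test has a true level of ≈ 0.040 at nominal 0.05 and loses ≈ 9 points of
BH sensitivity against the pooled test on equal-variance Gaussian
replicates, because its estimated degrees of freedom are themselves noisy
at such small n. The pooled test holds its nominal level exactly when
condition variances are comparable, which is the expected regime for
pre-normalized proteome replicates. `test = "welch"` remains available for
designs with genuinely heterogeneous variances. Proteins with fewer than 2
finite replicates in a condition are reported with NA statistics rather
than dropped; all-identical replicates in both conditions yield p = 1 with
a warning.

## What the synthetic cohorts emulate — and what they do not

The generator (`cohort_spec()` / `generate_cohort()`) draws log2
intensities from a single-factor-per-module model: members of a planted
module share one latent sample factor with loading `sqrt(rho_P)`, where
`rho_P = 2·sin(π·rho_S/6)` converts the requested Spearman correlation to
the Pearson correlation of the underlying Gaussian (the Gaussian
rank-correlation relation). A single factor per module is sufficient to
control pairwise correlation, cheap, and gives interpretable ground truth.
Missingness is a logistic function of the true log2 abundance
(`detection_slope` per standardized log2 unit; intercept calibrated
numerically to hit the requested global rate), so low-abundance proteins
are censored more often and steep slopes produce proteins missing in > 90 %
of samples — exercising the undefined-correlation policy the way sparsely
detected centromere proteins do in real atlases.

Defaults define the package's reference validation cohort: 1000 proteins ×
500 samples, one size-8 module at target Spearman 0.7, baseline log2
intensities N(14, 2) (MS-like intensity scale), 20 % global missingness
with slope 1. These sizes keep the full validation suite fast while leaving
the module signal realistically attenuated by censoring; the scale
behaviour is checked separately on a 15,000 × 1,200 cohort, the shape of
the largest published pan-cancer proteome atlases. The differential-stage
calibration uses 2000 null proteins at 4 + 4 replicates, sensitivity uses
50 two-fold proteins among 500 at σ = 0.2, and group recovery uses 4
proteins planted at fold 1.74 with σ = 0.1 — matching the magnitude of the
group-level changes such re-analyses report.

What the generator does **not** emulate: real intensity distributions
(heavy tails, batch effects), tissue or lineage substructure (which
produces correlated *blocks* of samples, not independent ones),
peptide-sharing artifacts between protein groups, or missingness that is
informative beyond abundance (e.g. run-level dropouts). Passing tests
therefore demonstrate that the statistics are implemented correctly and
recover known structure under idealized sparsity — not that any particular
real dataset carries a GBA signal of a given strength.

All generators take explicit integer seeds and restore the caller's RNG
state; there is no hidden global randomness, and identical seeds give
byte-identical pipeline outputs.

## Limitations

* Correlation is symmetric and confounded: a shared regulator, a shared
  lineage, or a technical covariate produces the same signal as a shared
  pathway. Ranked lists generate hypotheses, not interactions.
* Zero imputation biases correlations among co-sparse proteins upward when
  missingness itself is correlated; the undefined mask flags only the
  extreme (constant) case.
* The abundance-based analysis cannot distinguish complex stoichiometry
  from pathway co-regulation; the term-median statistic aggregates both.
* No ontology propagation is performed: annotation terms are used as flat
  sets, exactly as supplied.
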