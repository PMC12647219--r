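# gbamine

Guilt-by-association mining of wide proteome abundance matrices.

## The problem

Pan-cancer proteome resources quantify thousands of proteins across
hundreds to more than a thousand cell lines or patient samples. Proteins
that act in one pathway tend to rise and fall together across such cohorts,
so the abundance profile of a query protein carries a functional signal:
rank every other protein by how strongly it co-varies with the query and
the top of the list is enriched for pathway partners — *guilt by
association* (GBA). gbamine implements this workflow for anyone with a wide
protein × sample intensity table: computational biologists probing a
favourite protein, and proteomics groups validating whether a dataset's
co-variation structure is strong enough to support GBA at all.

## The method

For an abundance matrix `X` (proteins × samples, missing quantifications
explicit):

1. **Zero imputation.** Every missing cell becomes 0 ("not quantified" →
   "not detected"). This makes rank correlation computable for sparsely
   detected proteins; a protein that becomes constant after imputation has
   no defined correlation — such entries are set to 0 and tracked in an
   `undefined_mask` rather than silently mixed with real zeros.
2. **All-vs-all Spearman.** Each protein's sample vector is rank-transformed
   once (average ranks for ties, which matters because imputation creates
   massive ties at zero); the full matrix
   `rho[i,j] = cor(rank(x_i), rank(x_j))` is then a single standardized
   cross-product, tractable at 15,000 × 15,000. With no ties this equals
   `1 − 6Σd²/(n(n²−1))`.
3. **Ranked association lists.** For a query `q`, all proteins are ordered
   by descending `rho[q, ·]`; the query heads its own list at rank 1
   (`rho = 1`), ties break lexicographically. No significance cutoff is
   applied — the rank itself is the statistic.
4. **Validation statistics.** Per annotation term (e.g. a GO category), the
   median of all within-term pairwise correlations (pairs with `rho == 1`
   excluded); the distribution of those medians is compared with the median
   of *all* correlations in the dataset. Likewise, a curated pair set
   (e.g. synthetic-lethal partners) is compared with the background; the
   headline number is the **shift** = set median − background median.
5. **Panels and depletion experiments.** A named panel (e.g. centromere
   proteins + the NDC80 complex) can be profiled (sub-matrix, per-protein
   correlation and abundance quartiles, missingness), and a two-condition
   replicate experiment analysed as per-protein log2 fold change with
   two-sample t tests and Benjamini–Hochberg correction, plus group-level
   fold aggregation `2^mean(log2fc)` for a protein complex.

A synthetic-cohort generator plants correlated modules (single latent
factor per module, loading calibrated via `rho_S = (6/π)·asin(rho_P/2)`),
abundance-dependent detection-limit missingness, matched annotation terms,
pair sets and depletion experiments, so the entire pipeline is testable
with known ground truth and no downloads.

## Worked example

```r
library(gbamine)

co <- generate_cohort(cohort_spec(seed = 1))   # reference simulation
cm <- correlation_matrix(co$matrix)
top_k(rank_associations(cm, "P0001", dataset_label = "reference cohort"), 10)
```

```
abundance_matrix: 1000 proteins x 500 samples (100400 missing cells)
ranked_associations for query 'P0001' [reference cohort]: 10 proteins
   rank protein       rho
1     1   P0001 1.0000000
2     2   P0008 0.4130198
3     3   P0005 0.3814943
4     4   P0007 0.3619724
5     5   P0002 0.3436191
6     6   P0004 0.3334778
7     7   P0006 0.2943120
8     8   P0003 0.2690501
9     9   P0541 0.1279983
10   10   P0431 0.1198881
```

The cohort plants one size-8 correlated module (proteins P0001–P0008,
target within-module Spearman 0.7, attenuated here by 20 % detection-limit
missingness). All 7 partners of the query fill ranks 2–8, cleanly separated
from the first unrelated protein (rho ≈ 0.13) — the GBA signal the ranking
is designed to surface. The validation statistics on the same cohort:

```r
ps <- generate_pair_set(co$truth, n_planted = 20, n_null = 0, seed = 3)
pair_set_enrichment(cm, ps)
```

```
set_enrichment_result: 20 pairs in matrix (0 absent)
  set median 0.3817 vs background -0.000113 -> shift 0.3818
```

Truly co-functional pairs sit far above the background of all 499,500
correlations, whose median is ~0.

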