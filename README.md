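# anxclust

Hierarchical clustering of country-level pre-exam anxiety rates, with a
full cluster-validation suite and paired activity-group comparisons.

PISA 2018 recorded, for 56 countries, the percentage of 15-year-old
students reporting pre-exam anxiety, stratified by physical-activity
status (low vs high). `anxclust` is for epidemiologists and quantitative
social scientists who want to group countries by such indicators and
defend the grouping: it clusters the per-country percentages, validates
the partition, and tests per-country differences between activity groups.

## What it computes

Countries are clustered agglomeratively from pairwise Euclidean distances
(for one feature, |x_i − x_j|) under Ward, complete, average or single
linkage, using a deterministic nearest-neighbor-chain engine whose
dendrogram does not depend on input row order. The tree is cut either
into k clusters or at a fraction of its maximum merge height (default
20%). A partition is validated with:

- silhouette widths s(i) = (b(i) − a(i)) / max(a(i), b(i));
- WCSS = Σ_k Σ_{i∈C_k} (x_i − μ_k)², its average square distance WCSS/n
  and percentual WCSS √(WCSS/n);
- BCSS = Σ_k n_k (μ_k − μ)², the explained variation BCSS/TSS and the
  BCSS/WCSS ratio (with WCSS + BCSS = TSS enforced).

Per-country group differences use diff = p_high − p_low,
se_diff = √(se_low² + se_high²), Z = diff/se_diff and two-sided tiers at
|z| ≥ 1.96 / 2.58 / 3.29. A seeded synthetic generator with known cluster
structure plus an adjusted-Rand `recovery_score()` make every stage
testable end to end.

The three published country tables ship as fixtures
(`anx_fixture("table1_low")`, `"table2_high"`, `"table3_paired"`).

## Worked example

```r
library(anxclust)

t1 <- anx_fixture("table1_low")            # 56 countries, low activity
dn <- anx_agglomerate(anx_distances(t1), "ward")
part <- cut_at_fraction(dn, 0.20)
attr(part, "k")
#> [1] 5

q <- quality_report(t1, part)
q
#> <anx_quality> k = 5, n = 56
#>   mean silhouette        0.590
#>   WCSS                  310.17  (avg sq dist 5.54, percentual 2.35)
#>   BCSS                 6903.55  (avg per cluster 1380.71)
#>   explained variation      96%   BCSS/WCSS ratio 22.26
```

The five clusters are recovered at the 20% cut; 96% of the between-country
variance is captured, the within-cluster root-mean-square spread is about
2.35 percentage points, and the mean silhouette of 0.59 clears the usual
0.5 bar for a well-separated partition.

```r
rep <- run_analysis(analysis_config(
  low = "table1_low", high = "table2_high", paired = "table3_paired"
))
rep$groups$low$membership
#> # A tibble: 5 × 5
#>   label     n mean_pct mean_pct_rounded countries
#>   <chr> <int>    <dbl>            <dbl> <chr>
#> 1 H-1       9     77.9               78 Brazil; Dominican Republic; …
#> 2 H-2      16     67.1               67 Australia; Uruguay; Chinese …
#> 3 L-1      16     59.6               60 Chile; Denmark; Japan; Turke…
#> 4 L-2       7     51.6               52 Estonia; Israel; Lithuania; …
#> 5 L-3       8     41.4               41 Finland; Netherlands; German…
```

Clusters are labeled H-/L- (above/below the grand mean) in descending
order of their mean anxiety percentage; `rep$comparison` holds the
per-country Z tests (e.g. Austria: diff −7.0, Z −2.73, p < 0.01) and
`sensitivity_analysis()` confirms the 20% cut is stable against 15% and
25% alternatives. A thin command-line wrapper lives at
`inst/cli/anxclust.R`.

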