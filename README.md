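# clonepotency

Quantitative analysis of single-cell clonal assays of human
hematopoietic progenitors.

In these assays, single CD34+ progenitor cells (HSC, MPP, LMPP, MLP,
BNKP, CMP, GMDP, MDP, CDP) are sorted one per well, cultured, and their
progeny counted by flow cytometry in six terminal lineages:
granulocytes (G), monocytes (M), B/NK lymphocytes (L), CD141+
conventional dendritic cells (DC1), CD1c+ conventional dendritic cells
(DC2) and plasmacytoid dendritic cells (pDC). A clone's six-dimensional
yield vector — its *quantitative potency* — carries far more
information than the classical present/absent reading of potency, and
this package implements the statistical machinery to exploit it:

* **Bias statistics.** Per clone: commitment degree
  `c_k = y_k / Σ y_j`; the **equipotency ratio** (min/max over positive
  lineages; 1 = truly equipotent); the **bias ratio**
  (second-largest / largest yield; 0 = wholly biased); predominant
  lineage. Lineage positivity uses event thresholds of 7 (2 for CDP).
* **Normalization.** DESeq-style geometric-mean size factors across
  donors within each subset, and across lineage columns; `log10(y + 1)`
  scaling.
* **Embedding.** Perplexity-calibrated Gaussian affinities
  `P(i,j) = (P_{j|i} + P_{i|j}) / 2N` with per-clone bandwidths found by
  binary search, minimized into a 2-D map by exact-gradient t-SNE
  (Student-t kernel, KL objective); PCA; Spearman co-ancestry distances
  `d = 1 − ρ` between lineages with classical MDS.
* **Tracks.** Lineage backbones at ≥ 70% commitment, distance of every
  clone to the nearest backbone point, nearest-track assignment.
* **Clustering.** Complete-linkage hierarchical clustering, a k-cluster
  cut (default 4), and optimal leaf ordering (Bar-Joseph dynamic
  program) maximizing adjacent-leaf similarity.
* **Heritability.** Granddaughter families: ancestor potency inferred
  as the granddaughter sum, bias-inheritance vs switching calls,
  switch-direction matrices, commitment fold-changes.
* **Dosage correlations.** Pearson correlations between IRF8/PU.1
  gate-occupancy percentages and lineage-bias composition across
  subsets, with the exact Student transform `t = r√((n−2)/(1−r²))` for
  significance.
* **Synthetic data.** A seeded Dirichlet-multinomial generator
  reproducing the assay's structure (heavy-tailed yields,
  subset-specific bias archetypes, bias-yield coupling, heritable
  granddaughter bias), so the entire pipeline is testable end to end.

Functions take data frames first and return tibbles; result objects
have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(clonepotency)

params <- sim_params(n_clones = c(HSC = 120, CMP = 120, CDP = 80),
                     unproductive_fraction = c(HSC = 0.52, CMP = 0.6, CDP = 0.6),
                     seed = 1)
clones <- simulate_clone_table(params)

profiles <- bias_profiles(clones)
dplyr::select(profiles, clone_id, subset, total_yield, n_lineages,
              equipotency_ratio, bias_ratio, predominant)
#> # A tibble: 123 × 7
#>   clone_id subset total_yield n_lineages equipotency_ratio bias_ratio
#> 1 HSC_0003 HSC             49          2            0.5         0.5
#> 2 HSC_0004 HSC             29          2            1           1
#> 3 HSC_0006 HSC             35          3            0.438       0.562
#> 4 HSC_0007 HSC           1623          6            0.0514      0.570
#> 5 HSC_0008 HSC            501          6            0.241       0.883
#> # ℹ 118 more rows, 1 more variable: predominant <chr>
```

Clone `HSC_0007` produced 1,623 cells across all six lineages but with
an equipotency ratio of 0.05 — multipotent, yet strongly biased: the
central observation this analysis quantifies.

```r
potency_composition(clones)$efficiency
#> # A tibble: 3 × 5
#>   subset seeded productive efficiency     se
#> 1 CDP        80         28      0.35  0.0533
#> 2 CMP       120         40      0.333 0.0430
#> 3 HSC       120         55      0.458 0.0455
```

Clonal efficiency is the share of seeded wells that produced progeny,
with the standard error of proportion.

```r
emb <- embed_clones(clones, seed = 1, n_iter = 500)  # perplexity 20
glance(emb)
#> # A tibble: 1 × 6
#>       n kl_initial kl_final n_iter  seed perplexity
#> 1   123       1.67    0.699    500     1         20

tracks <- assign_clone_tracks(profiles, emb)
table(tracks$track)
#> DC1 DC2   G   M pDC
#>  28  30  22  10  33
```

The embedding reduced the Kullback–Leibler divergence from 1.67 to
0.70; each productive clone is then assigned to the lineage track whose
≥70%-commitment backbone lies nearest in the map (no clone in this
small run was ≥70% committed to L, so that backbone is empty and
flagged). `autoplot(emb, colour = tracks$track)` draws the map;
`run_pipeline(pipeline_config(seed = 1), "artifacts")` writes every
stage's CSV plus a manifest.

## Vignette

`vignettes/clonal-potency-methods.Rmd` documents the models, the
parameter defaults and why, the synthetic generator's assumptions and
limits, and the numerical design choices (tie-breaking, degenerate
inputs, tolerances).
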