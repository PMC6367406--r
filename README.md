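# tnbctype

Two-layer molecular classification of triple-negative breast cancer
(TNBC) from bulk gene-expression data.

TNBC — tumors lacking estrogen/progesterone receptor expression and HER2
overexpression — is molecularly heterogeneous, and its published subtype
schemes mix two distinct biological axes. `tnbctype` separates them. It
derives, from an expression matrix alone:

1. a **cellular classification** with four labels ordered along the
   differentiation axis of the cancer stem cell hypothesis — **LAR**
   (luminal androgen receptor), **basal**, **CLDN-high** and **CLDN-low**
   (claudin-low, the least differentiated), and
2. an orthogonal binary **immune layer** (**IM+ / IM−**),

plus nearest-centroid machinery to transfer both labelings to new
cohorts, and the survival statistics used to characterize the subgroups
(for instance, whether IM+ tumors relapse later than IM− tumors).

## Method

The pipeline is built from interpretable, individually testable stages:

- **Preprocessing** — per-sample magnitude (median) normalization, log2,
  one-way additive batch-effect removal, per-gene mean centering,
  probe-to-gene collapsing by maximal variance, and restriction to the
  2000 most variable genes.
- **Co-expression network** — a Chow–Liu tree-structured graphical
  model: pairwise Pearson correlations *r* are mapped to Gaussian mutual
  information *I = −½ log(1 − r²)* and a maximum-weight spanning forest
  is grown (Kruskal, deterministic tie-breaks), discarding edges below
  the MI of |r| = 0.3.
- **Functional nodes** — the forest is pruned into branches of 10–150
  genes; each branch is tested for gene-set over-representation
  (one-sided hypergeometric, Benjamini–Hochberg) against a user-supplied
  GMT and labeled by its top term.
- **Metanodes** — node activities (per-sample mean expression of node
  genes) are clustered with average linkage under correlation distance
  1 − r; cutting at 0.7 groups related nodes, and marker enrichment tags
  the luminal, basal and immune metanodes plus the single claudin
  functional node (which must carry CLDN3/CLDN4/CLDN7).
- **Sparse k-means calls** — for each of these four gene sets, samples
  are split high/low by Witten–Tibshirani sparse k-means (k = 2):
  alternating k-means on `X diag(√w)` with the weight update
  `w ∝ S(a, Δ)₊` under ‖w‖₂ = 1, ‖w‖₁ ≤ s, where `a` is the per-feature
  between-cluster sum of squares; `s` is chosen by a permutation gap
  statistic.
- **Decision workflow** — luminal-high → LAR; luminal-low & basal-high →
  basal; both low → CLDN-high or CLDN-low by the claudin-node call.
  Rare luminal+/basal+ double-positives are assigned LAR and flagged.
  The immune split is made independently and overlaps all four groups.
- **Transfer** — per-subgroup centroids (mean centered-log2 profiles
  over the metanode gene universes) assign new samples by maximal
  Pearson correlation.

A synthetic-cohort generator (planted equicorrelated modules, four
subtypes, an independent immune layer, batch shifts, label-dependent
exponential survival) makes every stage testable end to end without any
external download.

## Worked example

```r
library(tnbctype)

spec <- cohort_spec(seed = 42L)              # 400 tumors, 26 modules
sim  <- generate_expression(spec)            # expression + truth table
fit  <- tnbc_fit(sim$expression,
                 gene_sets = generate_genesets(spec),
                 control = tnbc_control(seed = 42L))
print(fit)
#> Two-layer TNBC classification fit
#>   400 samples, 734 genes, 14 functional nodes
#>   cellular: basal=252, CLDN-high=35, CLDN-low=41, LAR=72
#>   immune:   IM-=187, IM+=213
summary(fit)
#> Cellular classification (n = 400 ):
#>   basal       252 (63%)
#>   CLDN-high    35 (9%)
#>   CLDN-low     41 (10%)
#>   LAR          72 (18%)
#> Immune layer:
#>   IM-         187 (47%)
#>   IM+         213 (53%)
```

The fitted subtype mix recovers the planted 63/8/11/18% proportions; the
class counts differ from the truth only at the CLDN-low/CLDN-high
boundary, the weakest contrast (a single 34-gene node). The immune layer
has prognostic value in the matching simulated clinical table:

```r
clin <- generate_survival(sim$truth, default_hazard_map(sim$truth),
                          seed = 43L)
tnbc_survival(fit, clin, by = "immune")
#> survival_result: IM-=187, IM+=213
#>   log-rank chi2 = 6.579 (df = 1), p = 0.01032
#>   HR = 0.6895 (95% CI 0.5181-0.9175), reference = IM-
```

i.e. IM+ tumors relapse at ~0.69 times the IM− hazard (true simulated
hazard ratio 0.73). New cohorts are classified with
`predict(fit, new_expr)`; a full result bundle with a JSON manifest is
written by `run_pipeline()`.

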