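---
title: "Methods: the two-layer TNBC classification"
author: "tnbctype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-layer TNBC classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnbctype)
```

## The problem and the model

Triple-negative breast tumors do not form one molecular entity. Two
kinds of signal coexist in their bulk expression profiles: a *cellular*
axis — where along the mammary differentiation hierarchy the tumor's
expression programme sits (claudin-low and mesenchymal-like at one end,
luminal androgen-receptor-driven at the other) — and an *immune* axis
reflecting lymphocytic infiltration and antigen presentation, which is a
property of the microenvironment rather than of the tumor cell. Schemes
that cluster tumors on all genes at once entangle the two. The model
implemented here keeps them separate: the cellular label and the immune
label are called independently and every tumor carries both.

The pipeline first organizes genes, then classifies samples:

1. **Gene organization.** After normalization, the 2000 most variable
   genes are connected by a Chow–Liu-style maximum spanning forest over
   Gaussian mutual information $I(r) = -\tfrac12\log(1-r^2)$ of pairwise
   Pearson correlations. A tree-structured graphical model is the
   simplest dependence structure that is estimable at $p \gg n$, and its
   branches are exactly the tight co-expression neighbourhoods we need.
   Branches (10–150 genes) whose gene content is over-represented in a
   supplied annotation collection become *functional nodes*; nodes whose
   activity profiles (per-sample mean expression) correlate are grouped
   into *metanodes* by average-linkage clustering, and marker gene
   enrichment names the luminal, basal and immune metanodes and the
   single claudin functional node.
2. **Sample classification.** On each of those four gene sets, sparse
   k-means with $k=2$ splits samples into high/low activity groups, and
   a fixed decision workflow turns the three cellular calls into one of
   LAR, basal, CLDN-high, CLDN-low; the immune split is reported
   separately as IM+/IM−.

Assumptions worth stating: expression is approximately Gaussian on the
log2 scale within a subgroup (the MI identity and the correlation
distances rely on second moments only); batch effects are additive on
the log2 scale and label-independent; each metanode's activity is
bimodal enough that a two-group split is meaningful — $k=2$ is taken as
a fixed design constant here, not re-estimated per dataset.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `top_k` | 2000 | genes | working set for network inference; variance ranking after probe collapsing |
| `min_edge_weight` | $I(0.3) \approx 0.047$ | nats | drops associations weaker than $|r| = 0.3$, preventing spurious bridges between modules |
| `max_branch_size`, `min_branch_size` | 150, 10 | genes | ~26 nodes over 2000 genes averages ~77 genes/node; branches outside the window are split or set aside |
| `alpha` | 0.05 | — | BH-adjusted threshold for branch enrichment and role assignment |
| `cut_height` | 0.7 | 1 − r | metanodes merge while average inter-node correlation exceeds 0.3 |
| `s` | gap-selected | — | sparse k-means L1 bound in $(1, \sqrt p\,]$; 25-permutation gap statistic per metanode, overridable |
| `n_restarts` | 20 | — | k-means initialization sensitivity |
| `seed` | mandatory | — | every stochastic step derives from it; recorded in the manifest |

## Numerical choices

* **Ties and determinism.** Kruskal edges are sorted by decreasing
  weight with ties broken by the lexicographic endpoint pair; branch
  pruning deletes the lightest edge within oversized components with the
  same tie-break; probe collapsing and variance filtering break exact
  ties by the smaller identifier; centroid-assignment correlation ties
  go to the lexicographically first label with a warning. Two runs with
  one seed produce byte-identical outputs.
* **Cluster orientation.** The sparse k-means clusters are anonymous;
  the one with the larger mean metanode activity is "high". An exact
  mean tie orients every sample "low", with a warning.
* **Sparse k-means monotonicity.** The inner k-means is warm-started
  from the previous centers in the re-weighted space, which makes the
  weighted between-cluster sum of squares non-decreasing across
  alternations; this is asserted at run time (tolerance 1e−8), as are
  the weight constraints $\|w\|_2 = 1$, $\|w\|_1 \le s$.
* **Soft-threshold root.** The L1 constraint is met by 60 bisection
  steps on the threshold $\Delta$, well below float precision on the
  bracketing interval.
* **Degenerate inputs.** Zero-variance genes are rejected by name before
  correlation; $|r| \to 1$ is capped at $r^2 = 1-10^{-12}$ with a
  warning; constant activity rows and constant sample profiles are
  rejected (their correlations are undefined); batches with one sample
  cannot be mean-adjusted without destroying the observation and are
  left unchanged with a warning; a Cox comparison with an event-free
  group is flagged `converged = FALSE` instead of reporting a spuriously
  finite hazard ratio.
* **Rounding.** Reported percentages use half-away-from-zero rounding
  (`percent_report`), the convention of the subgroup tables this package
  reproduces.

## Open design decisions

Several steps are under-determined by the analysis being reproduced;
the choices made here, each overridable:

* "Magnitude normalization" is read as per-sample median scaling to the
  median of sample medians (the standard scale equalization for
  single-channel arrays); a mean-scaling variant is a flag away.
* The network learner is the Chow–Liu construction — the canonical
  high-dimensional tree model, exactly testable against brute-force
  enumeration of spanning trees.
* Batch removal is a one-way fixed-effect adjustment without
  covariates, as it runs before any labels exist; no empirical-Bayes
  shrinkage.
* Centering happens on the complete collapsed dataset before the
  variance filter, following the stage order of the preprocessing
  description.
* Branches are disjoint; a branch becomes a node with its *whole* gene
  list (not only the annotated subset).
* Metanode formation uses correlation distance and average linkage, the
  transcriptomics norm; the claudin entity is a functional node, not a
  metanode.
* Luminal+/basal+ double positives are assigned LAR — the workflow
  tests luminal first — and flagged `ambiguous`, so downstream analyses
  can include or exclude them.
* Centroid transfer uses Pearson correlation (robust to affine
  cross-platform shifts); Spearman via flag. New cohorts are
  preprocessed with their own scaling and centering before assignment.
* Clinical tests exclude rows with missing values per comparison and
  report the n actually used.

## What the synthetic generator does and does not emulate

`generate_expression()` plants: four cellular subtypes at the 18/63/11/8
percent mix over 400 samples; an immune layer drawn independently at
52% IM+ in every subtype; 26 modules (6 luminal, 5 basal, 4 immune, one
34-gene claudin node carrying CLDN3/4/7, 10 neutral) with a
single-latent-factor equicorrelation structure at $\rho = 0.8$; mean
role shifts of 1.0 log2 units; 200 unstructured noise genes; two
batches offset by 0.3 log2 units; and exponential relapse-free survival
at 0.012 events/month with an IM+ hazard ratio of 0.73, censored at
0.01/month and administratively at 120 months.

Two generator choices deserve their rationale. The residual noise sd is
0.35 log2 units, a typical within-subtype residual spread for log2
microarray intensities. And effect sizes are deliberately
*heterogeneous*: modules of one role carry fixed multipliers in
$[0.7, 1.3]$ (mean 1), and genes within a module carry loadings evenly
spread over $[0.5, 1.5]$ (mean 1). Real functional nodes respond with
unequal magnitudes, and this structure is what correlation-based
centroid transfer feeds on — with perfectly uniform shifts a role
centroid would be constant across its genes, and a Pearson correlation
against a constant profile is undefined in principle and noise in
practice. The mean-1 constraints keep the planted effect size at the
stated 1.0 log2 units.

Not emulated: probe-level artifacts beyond additive batch shifts,
platform-specific intensity saturation, copy-number-driven expression,
tumor purity gradients, and any continuous blending between subtypes —
planted labels are crisp. Passing the recovery suite therefore shows
the machinery is correct and well-conditioned under the stated model;
it does not certify performance on real cohorts, where group
separations are weaker and partly continuous.

## Problem sizes used by the test and acceptance suites

Unit tests run on constructed fixtures of a few dozen samples. The
recovery suite fits the full default cohort (400 samples, 734 genes,
26 planted modules) and transfers to an independent 150-sample cohort;
survival recovery uses two groups of 500 with a true hazard ratio of
0.5 and ~20% censoring, plus 200 null simulations of 100 samples for
the log-rank calibration check. Exhaustive oracles (spanning-tree
enumeration, all 2-partitions of six samples, hypergeometric pmf
summation) are kept at sizes where enumeration is exact and fast.

## Known limitations

* The cellular axis is a discretization of a continuum; samples near
  the luminal or claudin decision boundaries are the least stable calls
  (on synthetic data, residual label error concentrates at the
  CLDN-low/CLDN-high boundary, driven by a single 34-gene node).
* Role assignment needs informative markers: if two metanodes claim one
  role the fit stops with a report rather than guessing — refine the
  markers or the cut height.
* The survival module is deliberately univariate (two-group hazard
  ratios, log-rank); no multivariable or time-varying Cox models.
* Annotation is taken as given in the GMT — no ontology-graph
  propagation.
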