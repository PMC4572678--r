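---
title: "Exemplar-based gene selection: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exemplar-based gene selection: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apkl)
```

## The model

`mapkl()` selects a compact gene signature from a two-class expression
matrix under one working hypothesis: the significant end of a ranked
gene list is not a set of independent markers but a union of clusters
of co-behaving genes, and a single representative per cluster carries
essentially all the discriminative information of the list. The
estimator therefore separates *how many genes matter statistically*
(the permutation ranking and the top-N cut) from *how much redundancy
they contain* (the cluster-count estimate and the exemplar choice).

Four stages, each exposed as its own function:

1. **`maxt_adjusted()`** — pooled two-sample t per probe, with raw and
   step-down maxT family-wise-error-adjusted permutation p-values. The
   step-down construction takes, for every permutation, running maxima
   of permuted |t| from the bottom of the observed ranking upward, so
   that the adjusted p-value of a high-ranked probe is controlled
   against the whole family below it. Probes are ranked by descending
   |t|, not by adjusted p-value: at a few hundred to a thousand
   permutations the adjusted p-values tie heavily and would make the
   ranking arbitrary, while |t| is continuous.
2. **`select_top_n()`** — keeps the `N` best ranks; ties in |t| break
   lexically on the probe id, so selection is reproducible to the byte.
3. **`kl_cluster_count()`** — Ward-linkage hierarchical clustering of
   the gene rows, cut at each k, with the Krzanowski–Lai index
   `KL_k = |DIFF_k / DIFF_{k+1}|`,
   `DIFF_k = (k-1)^(2/p) W_(k-1) - k^(2/p) W_k` on the within-cluster
   sums of squares. The dimension exponent `2/p` uses p = number of
   samples, the dimension of the space the gene rows live in. The
   clustering algorithm driving the scan is in principle open; Ward
   linkage was chosen because it optimizes the same within-cluster
   sum-of-squares criterion the index is built on, and it is exposed
   through the function boundary rather than hard-wired deeper in.
4. **`ap_with_target_k()`** — affinity propagation with the shared
   preference bisected until the message-passing returns exactly the
   estimated cluster count. Affinity propagation is used (rather than,
   say, partitioning around medoids) because its exemplars are actual
   data genes selected by the optimization itself, which is the point
   of the method.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `N` | 200 | genes carried into clustering; should approximate the expected signature size — see the note on identifiability below |
| `B` | 1000 | label permutations; 1000 gives p-value granularity 1/1001, the floor `B >= 100` keeps adjusted p-values meaningful |
| `k_max` | 30 | largest cluster count scanned; capped at `N - 2` because `KL_k` needs `W` at `k_max + 1` points and at least one interior k |
| `lambda` | 0.9 | affinity-propagation damping in [0.5, 1); heavier damping converges more slowly but almost never oscillates |
| `max_iters` / `conv_window` | 1000 / 100 | iteration cap and the number of consecutive iterations with an unchanged exemplar set that declares convergence |
| `seed` | 1 | drives the permutation draw; the whole fit is deterministic given `(data, parameters)` |

For the surrounding modules: the stratified split accepts 10–90%
validation shares and rounds per-class counts half-up (40% of a 20/10
cohort gives exactly 8/4 validation samples); cyclic loess uses span
0.7 and one iteration by default; the SVM grids are cost `2^(-4..4)`
and, for the radial kernel, gamma `2^(-6..2)`, with ties resolved
toward the smallest cost then gamma; mutual information uses
`floor(sqrt(n_samples))` equal-width bins; ARACNE tolerances default to
`eps = 0` (additive) and `tau = 0.15` (multiplicative).

## The synthetic generator and what the tests show

`synth_dataset()` emulates the study shape used throughout validation:
20 control and 10 treated samples, 1000 genes, five planted clusters of
20 differentially expressed genes each, a class shift of 2 noise-sd and
within-cluster correlation 0.7 induced by a shared latent factor
(`x = sqrt(rho) f + sqrt(1 - rho) eps`, which hits the target pairwise
correlation exactly). Background genes are iid Gaussian. An
intensity-scale variant exponentiates base 2 so the log2 preprocessing
paths can be exercised.

The generator deliberately omits probe-level effects, saturation,
heteroscedasticity across the intensity range and batch structure.
Passing recovery tests therefore demonstrate that the pipeline's logic
is correct under its own model — clusters of correlated shifted genes
in Gaussian noise — not that it is robust to the full pathology of real
microarray data.

**Identifiability of the recovery test.** With 100 planted genes, an
analysis that keeps `N = 200` top genes necessarily drags in ~100
null genes selected for their spuriously large |t|. Those genes form a
diffuse blob that must occupy at least one cluster, capping exemplar
precision at k/(k+1) and destabilizing the cluster-count estimate
(empirically it lands on 2 — signal versus blob — or on 7 — signal
plus a split blob). The end-to-end recovery runs therefore use
`N = 100`, the size of the planted signature, where the question "are
the five clusters found and are the exemplars planted genes?" is
actually well-posed. On real data the same reasoning applies in
reverse: `N` should be chosen near the number of genes one believes
carry signal, and the KL profile (`plot(fit)`) inspected rather than
trusted blindly.

## Numerical choices

* **t statistics.** Pooled variance by default (the classical choice
  for permutation ranking), Welch by flag. Zero within-class variance
  is floored at `1e-12` times the probe's overall variance — the
  statistic stays finite and the probe is flagged instead of producing
  an infinite t that would dominate every maximum.
* **Permutation counting.** Observed statistics are computed through
  the same vectorized engine as the permuted ones, and exceedance
  counts use a relative tolerance of `1e-9`: complementary label
  assignments yield mathematically identical |t| through different
  floating-point paths, and exact `>=` would count them erratically.
  When `choose(n, n1) <= B` the procedure enumerates all assignments
  and p-values become exact counts (the identity included), with a
  message.
* **Affinity propagation ties.** Exactly tied similarities (e.g.
  duplicated points) make the messages oscillate symmetrically and no
  exemplar ever emerges. A deterministic perturbation of relative size
  `1e-12` is added to the similarity matrix — the same remedy reference
  implementations apply with random noise, made reproducible. The
  reported net similarity is computed from the unperturbed matrix.
* **Preference bisection.** The initial bracket is
  `[2 min(offdiag S), max(offdiag S)]`. The upper end does not always
  reach k = n (for tight groups the mutual similarities still win), so
  the bounds expand geometrically — toward and past zero above,
  times 4 below — before bisection proper, all within the 20-run
  budget. An unreachable target returns the closest solution with a
  warning flag, never an error, since the downstream pipeline can
  proceed with a near-miss cluster count.
* **Cyclic loess.** One pass of pairwise M-vs-A local regression
  removes essentially the whole systematic offset; afterwards the
  pair offsets sit at the smoother's noise floor and fluctuate there,
  so iterating is cheap insurance rather than a convergent sequence.
* **Mutual information.** Maximum-likelihood plug-in entropies on
  equal-width bins, in nats. The plug-in estimator's positive bias
  grows with bins²/n and is substantial at the default binning for
  large n; the CLR transform is insensitive to it because each entry is
  z-scored against its own row background, which carries the same bias.
  Interpret raw MI values comparatively, not absolutely.
* **Network distances.** Path-based centralities invert the weights
  (`d = 1/w`), the standard convention for affinity weights; closeness
  of an isolated node is 0, local transitivity of a degree-<2 node
  is 0. The weighted clustering coefficient is the arithmetic-mean
  edge-weight (Barrat) variant; the global transitivity is the
  triangle-over-triple ratio of the binarized graph.
* **Reporting precision.** Metrics print at two decimals (accuracy at
  one decimal on the percent scale), the convention of the
  classification tables this report format mirrors.

## Problem sizes used by the test-suite simulations

Chosen as the smallest sizes at which the quantities of interest are
stable: the family-wise-error check uses 200 null replicates of a
50-gene, 5-vs-5 design at B = 100 permutations; Krzanowski–Lai recovery
uses 100 replicates of three 20-gene clusters 10 sd apart; affinity
propagation is checked against exhaustive subset enumeration at up to 8
points; centralities against a Floyd–Warshall oracle at up to 12 nodes;
and the end-to-end recovery runs 50 replicates of the full reference
design (1000 genes, 20/10 samples, five planted clusters, N = 100,
B = 100).

## Known limitations

* Annotation is offline and table-driven; nothing validates the
  supplied identifiers against live databases.
* The exact-k bisection can legitimately fail on similarity structures
  where no shared preference yields the requested count; the flagged
  closest solution is returned.
* The KL index is scanned over dendrogram cuts, so its `W_k` sequence
  inherits Ward's greediness; a globally optimal k-partition could give
  slightly different within-cluster sums.
* Cross-validated metrics pool out-of-fold predictions into a single
  confusion matrix; fold-averaged variants (and their variance) are not
  reported.
* The SVM engine is fixed (e1071); only kernel, cost and gamma are part
  of the contract.
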