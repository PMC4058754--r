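---
title: "Attributed-graph classification of functional connectivity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributed-graph classification of functional connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Resting-state fMRI yields one BOLD time series per voxel. Group differences
in conditions such as ADHD are believed to express themselves in the
*topology* of the brain's functional connectivity network rather than in
any single regional signal. `agnet` implements a subject-level
classification pipeline built on that premise:

1. **Voxel selection.** Each in-mask voxel is scored by the power of its
   time series, $P(T) = \frac{1}{n}\sum_i t_i^2$, powers are min–max
   normalized to $[0,1]$ per subject, and only voxels at or above a power
   percentile (default 98, i.e. the top 2 %, ties included) are retained.
   Low-power voxels are mostly noise; their pairwise correlations add
   spurious edges.
2. **Nodes.** Surviving voxels are grouped by the label they carry in a
   functional ROI atlas (a CC200-style parcellation on real data). Each ROI
   that received at least one selected voxel becomes a node holding the
   unweighted mean series, mean world coordinate (mm), and mean normalized
   power of its members. Node counts therefore *differ* across subjects —
   ROIs with no active voxel are simply absent.
3. **Edges.** Two nodes are connected when the Pearson correlation of
   their mean series is positive and at least `corrTh`; the correlation is
   the edge weight. `corrTh` is the main tuning parameter and is swept over
   $\{0.30, 0.40, \dots, 0.90\}$ by the evaluation protocol.
4. **Signatures.** Every node carries the attribute tuple
   $\langle \deg(n), \deg(\mathrm{ngh}(n)), \mathrm{pow}(n),
   \mathrm{pow}(\mathrm{ngh}(n)), \mathrm{coord}(n)\rangle$: weighted
   degree (sum of incident edge weights), the descending-sorted degrees of
   its neighbors, its power, their powers, and its coordinate.

Two graphs are compared by matching nodes on their signatures. A node
pair's cost is $W \cdot [d_1,\dots,d_5]^T$ with $W = [0.2, 0.1, 0.2, 0.1,
0.4]$: degree difference and power difference (each normalized by the
training-set maximum and clamped to 1), the two sorted-profile distances
(zero-padded to equal length $L$, summed absolute differences divided by
$\max \cdot L$), and a spatial sigmoid

$$ d_5 = \frac{1}{1 + 300\,e^{-\lVert c_1 - c_2\rVert / 4}} $$

which is $1/301 \approx 0.0033$ for coincident nodes and approaches 1 for
distant ones, discouraging anatomically implausible matches. The graph
distance is the minimum total cost of assigning every node of the smaller
graph to a distinct node of the larger one (Munkres/Hungarian algorithm);
subjects are then embedded in two dimensions by metric-stress MDS and
classified with a polynomial-kernel SVM.

### A note on the sigmoid's sign

The spatial component is sometimes written with a positive exponent,
$1/(1 + 300 e^{+d/4})$, which *decreases* with distance — the opposite of
its stated purpose (distant nodes should be expensive to match, and every
qualitative property of the measure depends on that). `agnet` uses the
increasing form above as the correct reading; the decreasing variant
remains available via `distance_config(printed_sigmoid = TRUE)` for
comparison, but nothing in the package uses it.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `power_percentile` | 98 | voxel power cutoff; top $100-p$ % of in-mask voxels kept, ties included |
| `corr_threshold` | 0.5 | minimum (positive) Pearson correlation for an edge; swept 0.30–0.90 in evaluation |
| `weights` | 0.2/0.1/0.2/0.1/0.4 | signature component weights; spatial dominates, node terms outweigh neighborhood profiles |
| `sigmoid_scale`, `sigmoid_decay` | 300, 4 mm | spatial sigmoid constants; `decay` sets the mm scale at which matching costs rise (half cost at $4\ln 300 \approx 22.8$ mm) |
| `n_dims` | 2 | embedding dimension; two dimensions performed best for this method and keep the classifier simple |
| `degree`, `cost` | 3, 1 | SVM polynomial degree and regularization, the classic $(u^\top v + 1)^3$ kernel defaults |
| `gtom_steps` | 5 | neighborhood depth of the topological-overlap baseline |
| `pow_threshold` | 0.85 | cutoff of the high-power-node-fraction global feature |

The sigmoid constants are design constants, not fitted quantities; both are
exposed in `distance_config()` for sensitivity analysis.

## Design choices where the design was open

- **Node power uses normalized voxel powers.** Whether node power is the
  mean of raw or normalized voxel powers is underdetermined; `agnet` uses
  normalized powers so that $\mathrm{pow}(n) \in [0,1]$, consistent with
  the normalization of every other distance component.
- **Percentile semantics.** "Ranked at the 98th percentile or more" is
  read as *keep the top 2 % of voxels* (nearest-rank, ties at the cutoff
  included). This makes the degenerate all-equal input select everything
  rather than nothing, and selection is invariant to whether normalization
  happens before or after ranking (min–max is monotone).
- **Profile distance denominator.** The sorted neighbor-profile distance
  divides by `max_val * L` where `L` is the *padded* (common) length; with
  the alternative (unpadded) reading the component could exceed 1.
- **Self-dissimilarity.** The raw self-assignment cost of an $N$-node
  graph is $N \cdot 0.4/301 > 0$ because $d_5 > 0$ even for coincident
  nodes. The pairwise matrix used for MDS zeroes its diagonal (metric
  embedding requires zero self-dissimilarity); the raw value is kept as an
  attribute.
- **Embedding once per cohort, not per fold.** Distances and the MDS
  embedding never see labels, so embedding the cohort once and
  cross-validating only the SVM leaks nothing and matches the method's
  computational shape. Test subjects enter through a joint *transductive*
  embedding of the train+test distance matrix — no out-of-sample mapping
  is defined for this distance, and the SVM still only ever trains on
  training coordinates.
- **Normalization constants** (max degree/power) are computed per training
  set — per site in multi-site evaluation; test-set values exceeding a
  maximum are clamped so components stay in $[0,1]$.
- **Degenerate sweep cells.** A sweep cell whose specificity or
  sensitivity is zero means the classifier voted one class for everyone;
  such cells are flagged and excluded when the best training threshold is
  selected.
- **Class imbalance** is left unweighted; strongly asymmetric
  specificity/sensitivity on imbalanced cohorts is expected behavior of
  this protocol, not an error.
- **Baseline features are computed on binarized graphs** (the standard
  form of the comparison toolbox), with per-ROI voxel selection so that
  node counts — and hence feature lengths — are equal across subjects.
  The per-node reduction of the pairwise GTOM measure is the row mean.

## Numerical choices

- The Hungarian solver is the $O(n^2 m)$ shortest-augmenting-path form
  with dual potentials; any cost-minimal assignment is acceptable since
  only the total cost is consumed downstream (the optimum total is
  unique).
- MDS starts from the classical `cmdscale` solution and refines by SMACOF
  majorization, which decreases metric stress monotonically. Iteration
  stops at a relative stress change below $10^{-8}$ (with an absolute
  floor of $10^{-12}$ so exactly-realizable configurations terminate) or
  at `max_iter` (default $10^5$). The procedure is deterministic; the
  config seed is consumed only if a rank-deficient classical start needs
  jittered padding columns.
- Zero-variance series have undefined Pearson correlation; the package
  defines it as 0 with a warning (no edge at any positive threshold).
- An edgeless training set would make the degree normalizer 0; it is
  guarded to 1 with a warning, and an all-zero training set (degrees *and*
  powers) is an error.
- Sweep ties among equally good thresholds resolve to the smallest
  threshold.

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` generates NIfTI-compatible 4D volumes over a
12×12×12 grid (4 mm voxels) with 8 compact, disjoint ROIs of 20 voxels
inside a dilated brain mask. Per subject, zero-mean latent ROI series are
drawn from a group-specific correlation matrix: coupled ROI pairs sit at
0.8 in controls and at $0.8 - \texttt{effect\_size}$ in cases, against a
0.15 background. A planted 10 % of each ROI's voxels carry the latent at
amplitude 3 over noise of SD 0.5, so their power dominates and the 98th
percentile selection recovers them; all other in-mask voxels are noise.
Zero-mean latents are the faithful emulation of bandpass-filtered BOLD,
and make power reflect fluctuation amplitude. Sex alternates and carries
no effect unless `sex_effect > 0`.

This captures exactly the assumptions the pipeline relies on — power-
separable active voxels, ROI-coherent signals, group differences expressed
in inter-ROI correlation — and nothing else. It does *not* model
hemodynamics, physiological noise, motion, registration error, site
effects, or realistic parcellation granularity (8 ROIs vs ~190). Passing
the recovery tests therefore demonstrates the pipeline's correctness and
sensitivity under its own assumptions, not expected accuracy on real
cohorts, where effect sizes are far smaller and detection rates in the
60–75 % range are the realistic ceiling.

Validation problem sizes were chosen to exercise every stage at
desk scale: recovery cohorts use 20+20 subjects, 8 ROIs and 120
timepoints (LOOCV detection ≥ 85 % at `effect_size = 0.6` across 5 seeds,
and chance-level at `effect_size = 0`); protocol-shape checks use 8+8
training and 4+4 test subjects with 80 timepoints.

## Limitations

- The assignment distance is not guaranteed to satisfy the triangle
  inequality; metric MDS treats it as a dissimilarity, which is standard
  practice but means the embedding stress need not vanish even at large
  dimension.
- Transductive test embedding means test predictions depend (unlabeled)
  on the test cohort's composition; a Gower-style out-of-sample extension
  would remove this at the cost of departing from the evaluated protocol.
- With ~60-node graphs the exact Hungarian solve is fast; the
  implementation makes no attempt at the approximations very large graphs
  would need.
- The positive-only edge rule discards anticorrelations by design;
  alternative edge signs are deliberately not implemented.
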