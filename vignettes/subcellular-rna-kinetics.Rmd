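---
title: "Estimating subcellular RNA kinetics from pulse-chase in situ sequencing"
author: "subcellKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating subcellular RNA kinetics from pulse-chase in situ sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subcellKinetics)
```

# The measurement and the model

A pulse-chase metabolic labeling experiment marks the RNA made during a
short window (the pulse, default 1 h) and then follows that cohort through
time (the chase, default samples at 0, 1, 2, 4 and 6 h). Reading the
labeled molecules out by 3D in situ sequencing gives every detected
molecule a gene identity and a position inside a segmented cell, so the
cohort can be followed not only in abundance but through the cell:
nucleus, inner cytoplasm, cell periphery.

Per gene, four constants summarize this journey. The model is deliberately
minimal — zero-order synthesis and first-order decay:

- During the pulse, the labeled concentration obeys
  $dX/dt = \alpha - \beta X$ with $X(0) = 0$, giving
  $X_0 = (\alpha/\beta)(1 - e^{-\beta\tau})$ at the end of a pulse of
  length $\tau$. `estimateAlpha()` inverts this closed form; the
  zero-degradation limit $X_0/\tau$ is used (and flagged) when
  $\beta \le 0$.
- During the chase no new labeled RNA appears, $dX/dt = -\beta X$, so
  $\ln X(t)$ is linear in chase time with slope $-\beta$ (`fitBeta()`).
- The nuclear fraction $y(t)$ of labeled reads is modeled as linear,
  $y = -\lambda t + f_0$ (`fitLambda()`). $\lambda$ is a net
  nucleocytoplasmic redistribution rate: nuclear and cytoplasmic
  degradation are not separated, and no attempt is made to resolve them.
- The mean distance ratio of cytoplasmic reads,
  $\mathrm{DR} = d_n/(d_n + d_c)$, is modeled as linear in chase time with
  slope $\gamma$ (`fitGamma()`); the sign is kept, negative values meaning
  inward (membrane-to-nucleus) drift.

Concentrations are counts per voxel (voxel = 200 × 200 × 350 nm by
default), obtained by dividing each cell's normalized counts by its total
segmented volume in voxels; this removes the strong coupling between cell
size and read count before any fitting.

Units: $\alpha$ in copies/voxel/h, $\beta$ and $\lambda$ in 1/h, $\gamma$
in DR units/h.

## Assumptions worth stating

- All four rates are constant over the 6 h window (within a cell-cycle
  phase when estimation is phase-resolved).
- Synthesis stops sharply at the end of the pulse. Residual intracellular
  label can violate this shortly after washing; for that reason the 1 h
  chase sample is excluded from all fits by default
  (`PulseChaseDesign(excludedChaseHours = 1)`), and the simulator can
  inject a one-timepoint multiplicative inflation (`inflateChase`) so the
  benefit of the exclusion can be demonstrated rather than assumed — the
  test suite does exactly that.
- Reference (control) genes, probed for total rather than labeled RNA, are
  time-invariant. Each timepoint is rescaled so per-cell reference means
  agree across timepoints (`normalizeCounts()`, an idempotent transform;
  the grand target is the unweighted mean of per-timepoint means).
- A long-pulse steady-state sample, when present, is encoded as timepoint
  −1 in read tables so it can never silently enter a kinetic regression.

# Estimation choices where the convention was open

- **β fit form.** Log-linear OLS on mean concentrations is the default;
  `fitBeta(mode = "nls")` fits $A e^{-\beta t}$ by Levenberg–Marquardt
  least squares instead, reporting $R^2$ on the concentration scale. The
  QC gate (`qc_pass`) requires $\alpha > 0$, $\beta > 0$ and
  $R^2 \ge 0.5$ on the β fit; λ and γ are not gated by default, but their
  $R^2$ values are reported so callers can gate on them.
- **X₀ for the α inversion** is the observed mean concentration at chase
  0 when that timepoint is usable, else the fitted intercept of the β
  regression.
- **y(t)** is a ratio of sums (summed nuclear over summed nuclear +
  cytoplasmic reads) rather than a mean of per-cell ratios; the
  mean-of-ratios variant is available (`yMode`). Mean DR pools all
  cytoplasmic reads across cells at a timepoint.
- **Unweighted OLS** across timepoints; no per-timepoint cell-count
  weighting (a deliberate match to a plain regression call).

# Subcellular geometry

Distances are measured from voxel centers with the physical anisotropic
spacing (switchable to index units with `physical = FALSE`, replicating a
spacing-blind distance transform). For a cytoplasmic voxel, $d_n$ is the
distance to the nearest nucleus-labeled voxel of the same cell and $d_c$
the distance to the nearest voxel outside the cell. Under this transform
convention a voxel touching the nucleus has $d_n$ equal to one voxel pitch
(the minimum attainable), not zero. Only label *surfaces* are searched —
the nearest nucleus voxel seen from outside is always on the nucleus
surface — which makes the computation exact while avoiding an all-pairs
scan; the test suite checks it against a brute-force all-pairs oracle.

The middle/periphery cutoff is DR > 0.909, i.e. $d_n/d_c > 10$; ties go to
middle. Reads are assigned to cells purely by the voxel label, so a read
can never land in another cell's cytoplasm by construction.

# What the simulator emulates

`simulateExperiment()` generates molecule life histories with known rates
on a synthetic geometry of non-overlapping ellipsoidal cells with interior
nucleus ellipsoids (`makeCellGeometry()`):

- births: Poisson with rate α × phase multiplier × cell volume during the
  pulse, positions uniform over nucleus voxels; no synthesis afterwards;
- deaths: exponential lifetimes with hazard β;
- export: either `linear_fraction_schedule` (the expected nuclear fraction
  is *exactly* $\max(0, f_0 - \lambda t)$ — this exists so λ-recovery
  tests have an exact target) or `first_order_hazard` (nuclear survival
  $e^{-\lambda \cdot \text{age}}$, which declines but is not exactly
  linear);
- cytoplasmic position: deterministic DR drift,
  $\mathrm{DR}(t) = \mathrm{clip}(dr_0 + \gamma t)$ on the chase clock,
  realized by placing each molecule at the voxel whose DR is nearest the
  target. The drift is applied on the chase clock rather than per-molecule
  age so that the population mean — the only statistic the estimator uses —
  follows the stated line exactly. The physical mechanism of cytoplasmic
  RNA motion is unknown; this is a controlled stand-in, not a mechanistic
  claim;
- detection: independent thinning with probability
  `detectionEfficiency` (default 0.205);
- reference genes: time-constant expected counts, uniform over the whole
  cell;
- each chase timepoint is an independent realization over the same cell
  layout (destructive sampling of parallel dishes), so downstream stages
  treat (cell, timepoint) as one observed cell.

Ground-truth defaults (`geneTruthTable()`): α log-uniform on
[0.01, 0.08] copies/voxel/h (an expression-selected panel), β log-uniform
on [0.1, 1.0]/h (half-lives ~0.7–7 h), λ uniform on [0.02, 0.12]/h with
$f_0 = 0.85$, γ uniform on [−0.03, 0.06] DR/h with a drift origin
$dr_0 = 0.25$ chosen just above the smallest DR attainable on a cytoplasm
a few voxels thick, so the drift target stays inside the attainable range
over the whole chase. Phase fractions default to 50/25/25% (G1, G1/S,
G2/M); phase multipliers on α default to 1 — estimated from
concentrations, synthesis shows no substantial phase differences, so the
neutral default is the concentration-scale expectation. Per-phase effects
can be switched on through the multiplier columns.

## What passing recovery tests do and do not show

The recovery experiments (200 cells per timepoint × 50 genes; Spearman
between true and estimated rates at detection 1.0 and 0.2, computed by the
test suite and by `scripts/acceptance.R`) validate the estimator against
its own generative assumptions, with realistic sampling noise, detection
thinning and geometric quantization. They do not validate those
assumptions against real cells: the simulator has no segmentation errors,
no optical crowding, no probe-efficiency variation between genes, no
residual-label kinetics (beyond the optional one-point inflation), and no
cell-to-cell rate variability beyond Poisson counting.

Two intentional scale compromises of the synthetic geometry:

- cells are a few microns across (so that hundreds of cells fit in a
  test-sized volume); a cytoplasm this thin cannot reach DR > 0.909, so
  the periphery compartment stays essentially empty in simulations and its
  logic is exercised by direct fixtures instead;
- α is recovered on the detected scale (multiplied by the detection
  efficiency) — absolute efficiency is not identifiable from thinned
  counts, and reference normalization equalizes timepoints, not absolute
  scale. All rankings, correlations and clusterings are unaffected.

# Decoding layer

Barcodes are read in color space: each round reports the color of one
dinucleotide of anchor + barcode + anchor, under the standard 4-color
two-base map (configurable; identical pairs → 0, {AC,CA,GT,TG} → 1,
{AG,GA,CT,TC} → 2, {AT,TA,CG,GC} → 3). One anchor base on each side of a
5-nt barcode yields 6 readable rounds. Decoding rejects rather than
corrects: per round the L2-normalized 4-vector must have a unique argmax;
the quality score is the mean of −log(dominant value) (natural log,
configurable); a dot is assigned only on an exact codeword match with
quality ≤ `qMax` (default 0.5, set so that accepted-dot error stays well
below 1% at Gaussian channel noise of sd 0.2 — rejection absorbs errors).
Codebook construction fails loudly on color-sequence collisions.

# Cell-cycle phasing

`scoreGeneSet()` scores the printed G1/S (19 genes) and G2/M (18 genes)
marker panels against expression-matched controls: genes are binned by
average expression into 25 bins and 50 controls per set gene are drawn
from the matching bin (seeded). The control draws are kept per set gene —
a multiset rather than a deduplicated union — so the control pool's bin
composition mirrors the set's; with small panels whose markers crowd the
top expression bins, a deduplicated union systematically under-weights
those bins and biases the score. Cells with both scores ≤ 0 are G1;
otherwise the larger score wins, with exact ties going to G2/M under a
warning.

# Clustering and downstream analytics

Kinetic clustering z-scores each parameter (sample sd) across genes,
builds a kNN graph (Euclidean, k = 20 by default, union of directed
neighbor relations, unweighted) and partitions it with Louvain at
resolution 1.0 under a fixed seed. Clustering operates on the z-scored
parameter matrix directly; an embedding step before clustering is a
visualization choice, not an inference step, and is intentionally not part
of the pipeline. Covariation analysis fixes one gene order by
average-linkage hierarchical clustering on correlation distance (1 − r) of
the time-combined matrix and reuses that order for all per-timepoint
matrices. Gene-group comparisons use the two-sided Wilcoxon rank-sum test
(exact for small tie-free groups, normal approximation with tie correction
otherwise).

# Numerical and degenerate-input conventions

- Flat series: β (λ, γ) fits on constant inputs return slope 0 with $R^2$
  undefined (NA) and fail QC.
- Fewer than 3 usable timepoints, or fewer than 3 positive concentrations,
  flag the estimate as unusable instead of erroring.
- `computeDR` returns NA with a warning when $d_n + d_c = 0$.
- Zero-variance genes propagate as NA rows/columns in correlation matrices
  with a warning; zero-variance parameters refuse to z-score.
- All writers order rows deterministically, so pipeline outputs are
  diffable; identical simulator config + seed reproduces byte-identical
  read tables.

# Problem sizes

The shipped validation uses 200 cells per timepoint × 50 genes (plus 6
reference genes) on a 400 × 400 × 16 voxel grid, 10⁴ dots for decoding
accuracy, 200 cells for phase recovery and 100 genes × 10 seeds for
cluster recovery — sizes chosen to give stable Monte-Carlo estimates for a
desk-scale reproduction of the method.
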