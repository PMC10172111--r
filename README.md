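# subcellKinetics

Subcellular RNA kinetics from pulse-chase in situ sequencing.

Metabolic pulse-chase labeling (a short 5-EU pulse followed by timed chases)
combined with highly multiplexed 3D in situ sequencing yields, for every
detected RNA molecule, its gene identity, its age cohort (the chase
timepoint) and its position inside a segmented cell. From such data this
package estimates, per gene, the four rate constants that summarize the RNA
life cycle:

- **α** — synthesis rate (RNA concentration per hour, concentration in
  copies per voxel). During the pulse, `dX/dt = α − βX` with `X(0) = 0`, so
  the concentration at the end of a pulse of length τ is
  `X₀ = (α/β)(1 − e^(−βτ))`; α is recovered by inverting this closed form.
- **β** — first-order degradation rate (1/h). After the pulse no new labeled
  RNA is made, `dX/dt = −βX`, so β is minus the slope of `ln X(t)` over the
  chase, fit by ordinary least squares with an `R² ≥ 0.5` quality gate.
- **λ** — nuclear export rate (1/h): minus the slope of the nuclear read
  fraction `y(t) = nuclear/(nuclear + cytoplasmic)` regressed on chase time.
- **γ** — cytoplasmic translocation rate (DR units/h): the slope of the mean
  distance ratio `DR = d_n/(d_n + d_c)` of cytoplasmic reads over chase
  time, where `d_n` and `d_c` are a read's 3D distances to the nuclear
  surface and the cell membrane (anisotropic voxel spacing, 200 × 200 ×
  350 nm by default). DR is 0 at the nuclear surface and approaches 1 at
  the membrane; `DR > 0.909` (i.e. `d_n/d_c > 10`) defines the cytoplasmic
  "periphery", the rest is "middle".

Around this core the package provides: two-base color-space barcode
decoding with quality filtering (for pipelines that start at per-round dot
intensities), read-to-cell/compartment assignment from 3D label volumes,
reference-gene normalization across timepoints, cell-cycle phase scoring
(G1 / G1/S / G2/M) from nascent marker expression, phase-resolved kinetic
landscapes (up to 12 parameters per gene), kinetic gene clustering
(kNN graph + Louvain), gene-gene covariation over time, nucleocytoplasmic
matrix construction, and gene-group comparisons (e.g. m6A vs non-m6A) by
rank-sum tests. A pulse-chase simulator with known ground truth
(`simulateExperiment`) drives parameter-recovery validation end to end.

Counts live in a `CompartmentMatrix` (a `SummarizedExperiment` with
`nucleus`, `middle`, `periphery` and `total` assays); geometry in a
`SegmentationSet` of paired nucleus/cell label volumes on a `VoxelGrid`.

## Worked example

Simulate a small pulse-chase experiment (1 h pulse; 0, 1, 2, 4, 6 h chase;
detection efficiency 0.205), rebuild everything from the reads, and
estimate the kinetic constants:

```r
library(subcellKinetics)

seg   <- makeCellGeometry(VoxelGrid(c(200, 200, 16)), nCells = 40, seed = 1)
truth <- geneTruthTable(12, nReference = 4, seed = 2)
cfg   <- simConfig(40, truth, detectionEfficiency = 0.205, seed = 3)
sim   <- simulateExperiment(cfg, seg)

reads <- annotateReads(sim$reads[, c("gene","x","y","z","timepoint_h")], seg)
cm    <- buildCompartmentMatrix(reads, seg, genes = truth$gene)
cm    <- normalizeCounts(cm, truth$gene[truth$is_reference])

compartmentFractions(cm)
#>   timepoint_h   nucleus    middle periphery total_reads
#> 1           0 0.6197224 0.3802776         0        6916
#> 2           1 0.5313367 0.4686633         0        5409
#> 3           2 0.4727273 0.5272727         0        4950
#> 4           4 0.3414194 0.6585806         0        3875
#> 5           6 0.2633877 0.7366123         0        3436

est <- estimateAll(cm, PulseChaseDesign(), reads = reads)
head(round(est[, c("alpha","beta","lam","gamma","r2_beta")], 3))
#>   alpha  beta   lam  gamma r2_beta
#> 1 0.002 0.504 0.053  0.046   0.998
#> 2 0.009 0.151 0.077 -0.005   0.997
#> 3 0.006 0.227 0.030  0.030   0.999
#> 4 0.002 0.710 0.056 -0.017   0.986
#> 5 0.015 1.074 0.136  0.058   0.992
#> 6 0.015 0.174 0.030 -0.003   0.998
```

The nuclear fraction falls from 62% to 26% over the chase as labeled RNA is
exported, and per-gene β/λ/γ estimates track the generating values (gene 1
was simulated with β = 0.576, λ = 0.055, γ = 0.046). α is recovered on the
*detected* scale — multiplied by the detection efficiency — since absolute
efficiency is not identifiable from thinned counts; rankings and
comparisons across genes are unaffected. `qc_pass` in the estimate table
applies the positive-rate and `R² ≥ 0.5` gate. Downstream,
`parameterMatrix()` + `zscoreParameters()` + `clusterKinetics()` give
kinetic gene clusters, and `classifyCellCycle()` phases cells for
phase-resolved estimation (`estimateAll(..., byPhase = TRUE)`).

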