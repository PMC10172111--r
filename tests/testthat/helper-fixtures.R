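# Shared fixtures built in code. The small segmentation is cached per test
# run since several files use it.

.fixtureEnv <- new.env(parent = emptyenv())

smallSeg <- function() {
    if (is.null(.fixtureEnv$seg))
        .fixtureEnv$seg <- makeCellGeometry(VoxelGrid(c(96, 96, 14)),
                                            nCells = 9, seed = 101)
    .fixtureEnv$seg
}

# Hand-built single-cell segmentation on a tiny grid: a box cell with a box
# nucleus, for exhaustive brute-force oracles.
boxSeg <- function(spacing = c(200, 200, 350)) {
    sh <- c(12L, 12L, 8L)
    nuc <- array(0L, sh); cel <- array(0L, sh)
    cel[3:10, 3:10, 2:7] <- 1L
    nuc[5:8, 5:8, 3:6] <- 1L
    SegmentationSet(VoxelGrid(sh, spacing), nuc, cel)
}

# Brute-force distance oracle: all-pairs search over the full volume.
bruteFields <- function(seg, physical = TRUE) {
    sp <- if (physical) voxelSpacing(seg) else c(1, 1, 1)
    nuc <- nucleusLabels(seg); cel <- cellLabels(seg)
    sh <- dim(cel)
    coords <- arrayInd(seq_len(prod(sh)), sh)
    phys <- sweep(coords - 1L, 2, sp, `*`)
    cyto <- which(cel > 0L & nuc == 0L)
    d_n <- d_c <- numeric(length(cyto))
    for (i in seq_along(cyto)) {
        v <- cyto[i]; k <- cel[v]
        nucK <- which(nuc == k)
        outK <- which(cel != k)
        dd <- function(set) {
            d2 <- (phys[set, 1] - phys[v, 1])^2 +
                (phys[set, 2] - phys[v, 2])^2 +
                (phys[set, 3] - phys[v, 3])^2
            sqrt(min(d2))
        }
        d_n[i] <- dd(nucK)
        d_c[i] <- dd(outK)
    }
    data.frame(idx = cyto, d_n = d_n, d_c = d_c)
}

# Build a CompartmentMatrix directly from dense compartment count matrices.
toyCM <- function(nucleus, middle, periphery, timepoint_h, volume_voxels,
                  phase = NA_character_) {
    genes <- rownames(nucleus)
    cells <- sprintf("cell%02d", seq_len(ncol(nucleus)))
    asSp <- function(m) {
        dimnames(m) <- list(genes, cells)
        as(Matrix::Matrix(m * 1.0, sparse = TRUE) * 1, "CsparseMatrix")
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(nucleus = asSp(nucleus), middle = asSp(middle),
                      periphery = asSp(periphery),
                      total = asSp(nucleus + middle + periphery)),
        colData = S4Vectors::DataFrame(
            cell_id = seq_len(ncol(nucleus)), timepoint_h = timepoint_h,
            volume_voxels = volume_voxels, phase = phase,
            row.names = cells))
    new("CompartmentMatrix", se)
}

# Dense gene x timepoint concentration series as a CompartmentMatrix with
# one unit-volume cell per timepoint (all counts nuclear), so the mean
# concentration at each timepoint equals the given series exactly.
seriesCM <- function(X, t) {
    nuc <- X
    rownames(nuc) <- rownames(X)
    toyCM(nuc, middle = X * 0, periphery = X * 0, timepoint_h = t,
          volume_voxels = rep(1, length(t)))
}
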