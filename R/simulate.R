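#' @importFrom stats rlnorm quantile median complete.cases
NULL

.clip <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Sample a ground-truth kinetic parameter table
#'
#' Draws per-gene kinetic constants for the simulator. Defaults emulate an
#' expression-selected panel read out by pulse-chase labeling: synthesis
#' \code{alpha} log-uniform on [0.01, 0.08] copies/voxel/h, degradation
#' \code{beta} log-uniform on [0.1, 1.0]/h (half-lives of roughly 0.7 to 7
#' h), nuclear-fraction decline \code{lam} uniform on [0.02, 0.12]/h with
#' initial nuclear fraction \code{f0} = 0.85, and cytoplasmic DR drift
#' \code{gamma} uniform on [-0.03, 0.06] DR/h (a small minority of genes
#' drift inward). The drift origin \code{dr0} = 0.25 sits just above the
#' smallest DR attainable on a cell a few voxels thick (the voxel nearest
#' the nucleus already has DR about 0.13), so the drift target stays inside
#' the attainable range for the whole chase. Reference (control) genes
#' mimic probes against total RNA:
#' time-invariant expected counts (\code{beta} = 0), positions uniform over
#' the whole cell.
#'
#' @param nGenes number of kinetic (labeled) genes.
#' @param nReference number of constant-expression reference genes.
#' @param seed RNG seed.
#' @param f0 initial nuclear fraction at chase 0.
#' @param dr0 cytoplasmic DR at chase 0 (drift origin).
#' @return data.frame with columns gene, alpha, beta, lam, gamma, f0, dr0,
#'   is_reference, mult_g1, mult_g1s, mult_g2m (per-phase multipliers on
#'   alpha; default 1).
#' @examples
#' head(geneTruthTable(5, 2, seed = 1))
#' @export
geneTruthTable <- function(nGenes, nReference = 6L, seed = 1L,
                           f0 = 0.85, dr0 = 0.25) {
    set.seed(seed)
    g <- sprintf("GENE%03d", seq_len(nGenes))
    r <- if (nReference > 0L) sprintf("REF%02d", seq_len(nReference))
         else character(0)
    data.frame(
        gene = c(g, r),
        alpha = c(exp(runif(nGenes, log(0.01), log(0.08))),
                  rep(0.04, nReference)),
        beta = c(exp(runif(nGenes, log(0.1), log(1.0))), rep(0, nReference)),
        lam = c(runif(nGenes, 0.02, 0.12), rep(0, nReference)),
        gamma = c(runif(nGenes, -0.03, 0.06), rep(0, nReference)),
        f0 = f0, dr0 = dr0,
        is_reference = rep(c(FALSE, TRUE), c(nGenes, nReference)),
        mult_g1 = 1, mult_g1s = 1, mult_g2m = 1,
        stringsAsFactors = FALSE)
}

#' Configure a pulse-chase simulation
#'
#' Defaults reproduce the HeLa-style study conditions: a 1 h pulse followed
#' by 0, 1, 2, 4 and 6 h chase samples, detection efficiency 0.205, the
#' linear nuclear-fraction export schedule (the export model the estimator
#' assumes), deterministic DR drift, and a cycling-culture phase mix of 50%
#' G1, 25% G1/S, 25% G2/M.
#'
#' @param nCells number of cells in the geometry; each chase timepoint is an
#'   independent realization over the same cells (destructive sampling of
#'   parallel dishes sharing one layout).
#' @param geneTruth a data.frame as returned by \code{\link{geneTruthTable}}.
#' @param pulseHours,chaseHours pulse duration and chase times (h).
#' @param detectionEfficiency per-molecule detection probability in (0, 1].
#' @param exportMode \code{"linear_fraction_schedule"} (expected nuclear
#'   fraction exactly max(0, f0 - lam t)) or \code{"first_order_hazard"}
#'   (nuclear survival exp(-lam age); fraction declines but is not linear).
#' @param translocationMode \code{"dr_drift"} (cytoplasmic DR = clip(dr0 +
#'   gamma t)) or \code{"none"} (uniform over the cytoplasm).
#' @param phaseFractions P(G1), P(G1/S), P(G2/M); must sum to 1.
#' @param seed RNG seed; identical config + seed yields identical reads.
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(nCells, geneTruth, pulseHours = 1,
                      chaseHours = c(0, 1, 2, 4, 6),
                      detectionEfficiency = 0.205,
                      exportMode = "linear_fraction_schedule",
                      translocationMode = "dr_drift",
                      phaseFractions = c(0.5, 0.25, 0.25), seed = 1L) {
    new("SimConfig", nCells = as.integer(nCells), geneTruth = geneTruth,
        pulseHours = as.numeric(pulseHours),
        chaseHours = as.numeric(chaseHours),
        detectionEfficiency = as.numeric(detectionEfficiency),
        exportMode = exportMode, translocationMode = translocationMode,
        phaseFractions = as.numeric(phaseFractions), seed = as.integer(seed))
}

# Draw voxels uniformly within each cell for a vector of molecules.
# cellOf: cell id per molecule; voxlist: list (by cell id as character) of
# candidate linear voxel indices. Returns linear voxel index per molecule.
.sampleVoxels <- function(cellOf, voxlist) {
    out <- integer(length(cellOf))
    for (k in unique(cellOf)) {
        sel <- cellOf == k
        v <- voxlist[[as.character(k)]]
        out[sel] <- v[sample.int(length(v), sum(sel), replace = TRUE)]
    }
    out
}

# Nearest-DR voxel lookup: for molecules in cell k with target DR values,
# pick the cytoplasmic voxel of k whose DR is closest to the target.
.voxelsAtDR <- function(cellOf, target, drlist) {
    out <- integer(length(cellOf))
    for (k in unique(cellOf)) {
        sel <- which(cellOf == k)
        e <- drlist[[as.character(k)]]      # list(dr = sorted, idx = aligned)
        pos <- findInterval(target[sel], e$dr)
        lo <- pmax(pos, 1L)
        hi <- pmin(pos + 1L, length(e$dr))
        useHi <- abs(e$dr[hi] - target[sel]) < abs(e$dr[lo] - target[sel])
        out[sel] <- e$idx[ifelse(useHi, hi, lo)]
    }
    out
}

#' Simulate a pulse-chase in situ sequencing experiment
#'
#' Generates per-molecule life histories with known kinetics on a given cell
#' geometry and emits the detected reads at each chase timepoint together
#' with the ground truth. Per cell and gene, molecule births during the
#' pulse follow a Poisson process with rate alpha x phase multiplier x cell
#' volume (concentration x volume = expected copies); there is no synthesis
#' after the pulse. Each molecule decays with first-order hazard beta. Birth
#' positions are uniform over the cell's nucleus voxels; exported molecules
#' are placed at the cytoplasmic voxel whose DR is nearest the gene's drift
#' value clip(dr0 + gamma t). Surviving molecules are detected independently
#' with probability \code{detectionEfficiency}. Reference genes emit
#' time-constant expected counts uniformly over the whole cell.
#'
#' Each chase timepoint is an independent realization (parallel dishes
#' sharing the same segmentation layout), so downstream stages treat the
#' (cell, timepoint) pair as one observed cell.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param geometry a \linkS4class{SegmentationSet} with at least one cell.
#' @param inflateChase optional chase time (h) whose expected read count is
#'   multiplied by \code{inflateFactor}, emulating a residual-label artifact
#'   at that timepoint for robustness experiments.
#' @param inflateFactor multiplicative inflation (default 1 = none).
#' @return list with \code{reads} (data.frame: gene, x, y, z, timepoint_h,
#'   cell_id, compartment, dr, quality) and \code{truth} (list: gene_truth,
#'   cell_phase, cell_volume_voxels, tallies with born/alive/degraded/
#'   detected per gene x timepoint).
#' @export
simulateExperiment <- function(cfg, geometry, inflateChase = NA_real_,
                               inflateFactor = 1) {
    validObject(cfg)
    cel <- cellLabels(geometry)
    if (max(cel) < 1L) stop("geometry contains no labeled cells")
    set.seed(cfg@seed)

    gt <- cfg@geneTruth
    vols <- cellVolumes(geometry)
    nCells <- nrow(vols)
    sh <- voxelShape(geometry)
    tau <- cfg@pulseHours
    eff <- cfg@detectionEfficiency
    cutoff <- 0.909

    nuc <- nucleusLabels(geometry)
    nucIdxAll <- which(nuc > 0L)
    nucList <- split(nucIdxAll, nuc[nucIdxAll])
    celIdxAll <- which(cel > 0L)
    celList <- split(celIdxAll, cel[celIdxAll])

    fields <- distanceFields(geometry)
    drByVoxel <- numeric(prod(sh))
    drByVoxel[fields$idx] <- fields$dr
    drlist <- lapply(split(fields[, c("idx", "dr")], fields$cell),
                     function(d) {
                         o <- order(d$dr)
                         list(dr = d$dr[o], idx = d$idx[o])
                     })
    cytoList <- split(fields$idx, fields$cell)

    phases <- sample(c("G1", "G1/S", "G2/M"), nCells, replace = TRUE,
                     prob = cfg@phaseFractions)
    multMat <- rbind(gt$mult_g1, gt$mult_g1s, gt$mult_g2m) # 3 x nGenes
    phaseIdx <- match(phases, c("G1", "G1/S", "G2/M"))

    ng <- nrow(gt)
    gidx <- rep(seq_len(ng), times = nCells)
    cidx <- rep(seq_len(nCells), each = ng)
    rate <- gt$alpha[gidx] * multMat[cbind(phaseIdx[cidx], gidx)] *
        vols$total_voxels[cidx]   # expected copies per h during pulse
    isRef <- gt$is_reference[gidx]

    readList <- list()
    tallyList <- list()
    for (t in cfg@chaseHours) {
        lamTau <- rate * tau
        if (!is.na(inflateChase) && t == inflateChase)
            lamTau <- lamTau * inflateFactor
        n <- rpois(length(lamTau), lamTau)
        M <- sum(n)
        g <- rep(gidx, n)
        cc <- rep(cidx, n)
        ref <- gt$is_reference[g]

        u <- runif(M, 0, tau)               # birth time within the pulse
        age <- tau + t - u
        pSurv <- ifelse(ref, 1, exp(-gt$beta[g] * age))
        alive <- runif(M) < pSurv
        det <- alive & (runif(M) < eff)

        born <- rowsum(n, gidx)[, 1L]
        aliveTally <- tabulate(g[alive], nbins = ng)
        detTally <- tabulate(g[det], nbins = ng)
        tallyList[[length(tallyList) + 1L]] <- data.frame(
            gene = gt$gene, timepoint_h = t, born = as.integer(born),
            alive = aliveTally, degraded = as.integer(born) - aliveTally,
            detected = detTally)

        if (!any(det)) next
        gd <- g[det]; cd <- cc[det]; aged <- age[det]; refd <- ref[det]

        pNuc <- numeric(sum(det))
        if (cfg@exportMode == "linear_fraction_schedule") {
            pNuc <- .clip(gt$f0[gd] - gt$lam[gd] * t)
        } else {
            pNuc <- exp(-gt$lam[gd] * aged)
        }
        inNucleus <- !refd & (runif(length(gd)) < pNuc)

        vox <- integer(length(gd))
        if (any(inNucleus))
            vox[inNucleus] <- .sampleVoxels(cd[inNucleus], nucList)
        if (any(refd))
            vox[refd] <- .sampleVoxels(cd[refd], celList)
        cytop <- !refd & !inNucleus
        if (any(cytop)) {
            if (cfg@translocationMode == "dr_drift") {
                target <- .clip(gt$dr0[gd[cytop]] + gt$gamma[gd[cytop]] * t)
                vox[cytop] <- .voxelsAtDR(cd[cytop], target, drlist)
            } else {
                vox[cytop] <- .sampleVoxels(cd[cytop], cytoList)
            }
        }

        nucHere <- nuc[vox] > 0L
        drHere <- ifelse(nucHere, NA_real_, drByVoxel[vox])
        comp <- ifelse(nucHere, "nucleus",
                       ifelse(drHere > cutoff, "periphery", "middle"))
        a <- arrayInd(vox, sh)
        readList[[length(readList) + 1L]] <- data.frame(
            gene = gt$gene[gd], x = a[, 1L] - 1L, y = a[, 2L] - 1L,
            z = a[, 3L] - 1L, timepoint_h = t, cell_id = cd,
            compartment = comp, dr = drHere, quality = NA_real_,
            stringsAsFactors = FALSE)
    }

    reads <- if (length(readList)) do.call(rbind, readList) else
        data.frame(gene = character(), x = integer(), y = integer(),
                   z = integer(), timepoint_h = numeric(),
                   cell_id = integer(), compartment = character(),
                   dr = numeric(), quality = numeric())
    rownames(reads) <- NULL
    truth <- list(gene_truth = gt, cell_phase = phases,
                  cell_volume_voxels = vols,
                  tallies = do.call(rbind, tallyList))
    list(reads = reads, truth = truth)
}

#' Simulate a phase-structured nascent expression matrix
#'
#' Builds a normalized gene x cell expression matrix in which cells of a
#' given cell-cycle phase have their phase's marker genes inflated by a
#' common fold change over a lognormal background, emulating the nascent
#' expression signal that drives phase classification. G1 cells carry no
#' inflation.
#'
#' @param nCells number of cells.
#' @param g1s,g2m marker gene name vectors (defaults: the printed marker
#'   lists, see \code{\link{g1sMarkers}}).
#' @param nBackground number of non-marker background genes.
#' @param foldChange marker inflation in the matching phase (default 3).
#' @param phaseFractions P(G1), P(G1/S), P(G2/M).
#' @param seed RNG seed.
#' @return list with \code{expr} (gene x cell matrix) and \code{phase}
#'   (true phase per cell).
#' @export
simulatePhaseExpression <- function(nCells = 200L, g1s = g1sMarkers(),
                                    g2m = g2mMarkers(), nBackground = 400L,
                                    foldChange = 3,
                                    phaseFractions = c(0.5, 0.25, 0.25),
                                    seed = 1L) {
    set.seed(seed)
    genes <- c(g1s, g2m, sprintf("BG%04d", seq_len(nBackground)))
    base <- rlnorm(length(genes), meanlog = 0, sdlog = 0.4)
    phase <- sample(c("G1", "G1/S", "G2/M"), nCells, replace = TRUE,
                    prob = phaseFractions)
    lam <- outer(base, rep(1, nCells))
    lam[genes %in% g1s, phase == "G1/S"] <-
        lam[genes %in% g1s, phase == "G1/S"] * foldChange
    lam[genes %in% g2m, phase == "G2/M"] <-
        lam[genes %in% g2m, phase == "G2/M"] * foldChange
    expr <- matrix(rpois(length(lam), lam * 10) / 10, nrow = length(genes),
                   dimnames = list(genes, sprintf("cell%04d", seq_len(nCells))))
    list(expr = expr, phase = phase)
}
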