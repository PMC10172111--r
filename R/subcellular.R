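#' @importFrom stats runif rpois rbinom rexp rnorm setNames
NULL

# Linear-index pairs (i, j) of 6-adjacent voxels whose labels differ.
# Returns a list with indices and the two labels; used to extract label
# surfaces without scanning the volume once per cell.
.adjacentDiffPairs <- function(lab) {
    d <- dim(lab)
    strides <- c(1L, d[1L], d[1L] * d[2L])
    out <- vector("list", 3L)
    for (ax in 1:3) {
        keep <- slice.index(lab, ax) < d[ax]
        i <- which(keep)
        j <- i + strides[ax]
        li <- lab[i]; lj <- lab[j]
        ne <- li != lj
        out[[ax]] <- list(i = i[ne], j = j[ne], li = li[ne], lj = lj[ne])
    }
    list(i = c(out[[1L]]$i, out[[2L]]$i, out[[3L]]$i),
         j = c(out[[1L]]$j, out[[2L]]$j, out[[3L]]$j),
         li = c(out[[1L]]$li, out[[2L]]$li, out[[3L]]$li),
         lj = c(out[[1L]]$lj, out[[2L]]$lj, out[[3L]]$lj))
}

# Surface voxels of each label: label-k voxels with a 6-neighbor not labeled
# k. Returns data.frame(idx, cell).
.labelSurface <- function(lab) {
    p <- .adjacentDiffPairs(lab)
    ii <- c(p$i[p$li > 0L], p$j[p$lj > 0L])
    ll <- c(p$li[p$li > 0L], p$lj[p$lj > 0L])
    unique(data.frame(idx = ii, cell = ll))
}

# Exterior shell of each label: voxels NOT labeled k that are 6-adjacent to a
# label-k voxel (the discrete "membrane" seen from inside the cell).
.labelShell <- function(lab) {
    p <- .adjacentDiffPairs(lab)
    ii <- c(p$i[p$lj > 0L], p$j[p$li > 0L])
    ll <- c(p$lj[p$lj > 0L], p$li[p$li > 0L])
    unique(data.frame(idx = ii, cell = ll))
}

# Minimum Euclidean distance from each row of P to the point set Q
# (physical coordinates, rows = points).
.minDist <- function(P, Q) {
    D2 <- outer(rowSums(P^2), rep(1, nrow(Q))) +
        outer(rep(1, nrow(P)), rowSums(Q^2)) - 2 * tcrossprod(P, Q)
    D2[D2 < 0] <- 0
    sqrt(D2[cbind(seq_len(nrow(P)), max.col(-D2, ties.method = "first"))])
}

.idxToCoord <- function(idx, sh) {
    a <- arrayInd(idx, sh)
    a - 1L   # 0-based voxel indices
}

#' Per-voxel nuclear and membrane distances for cytoplasmic voxels
#'
#' For every cytoplasmic voxel (cell label > 0, nucleus label 0) computes the
#' shortest Euclidean distance from its center to the nearest nucleus-labeled
#' voxel of the same cell (\code{d_n}) and to the nearest voxel outside the
#' cell (\code{d_c}), plus the distance ratio \code{dr = d_n / (d_n + d_c)}.
#' Distances use the physical (anisotropic) voxel spacing by default; set
#' \code{physical = FALSE} to measure in voxel index units, replicating a
#' distance transform that ignores spacing.
#'
#' The nearest nucleus voxel is always on the nucleus surface and the nearest
#' outside voxel is always 6-adjacent to the cell, so only those surface sets
#' are searched; the result is exact (equal to an all-pairs search).
#'
#' @param seg a \linkS4class{SegmentationSet}.
#' @param physical use physical spacing in nm (default TRUE).
#' @return data.frame with one row per cytoplasmic voxel: \code{cell},
#'   \code{idx} (linear index into the volume), \code{x,y,z} (0-based voxel
#'   indices), \code{d_n}, \code{d_c}, \code{dr}.
#' @export
distanceFields <- function(seg, physical = TRUE) {
    sh <- voxelShape(seg)
    sp <- if (physical) voxelSpacing(seg) else c(1, 1, 1)
    nuc <- nucleusLabels(seg)
    cel <- cellLabels(seg)
    cyto <- which(cel > 0L & nuc == 0L)
    if (length(cyto) == 0L) {
        out <- data.frame(cell = integer(), idx = integer(), x = integer(),
                          y = integer(), z = integer(), d_n = numeric(),
                          d_c = numeric(), dr = numeric())
        attr(out, "shape") <- sh
        return(out)
    }
    ccell <- cel[cyto]
    nsurf <- .labelSurface(nuc)
    shell <- .labelShell(cel)

    co <- .idxToCoord(cyto, sh)
    phys <- function(cm) sweep(cm, 2L, sp, `*`)
    ord <- order(ccell)
    cyto <- cyto[ord]; ccell <- ccell[ord]; co <- co[ord, , drop = FALSE]
    runs <- rle(ccell)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L

    nsurf_split <- split(nsurf$idx, nsurf$cell)
    shell_split <- split(shell$idx, shell$cell)
    d_n <- numeric(length(cyto)); d_c <- numeric(length(cyto))
    for (r in seq_along(runs$values)) {
        k <- runs$values[r]
        sel <- starts[r]:ends[r]
        P <- phys(co[sel, , drop = FALSE])
        ns <- nsurf_split[[as.character(k)]]
        if (is.null(ns)) {
            warning("cell ", k, " has no nucleus voxels; d_n set to NA")
            d_n[sel] <- NA_real_
        } else {
            d_n[sel] <- .minDist(P, phys(.idxToCoord(ns, sh)))
        }
        sc <- shell_split[[as.character(k)]]
        d_c[sel] <- .minDist(P, phys(.idxToCoord(sc, sh)))
    }
    out <- data.frame(cell = ccell, idx = cyto, x = co[, 1L], y = co[, 2L],
                      z = co[, 3L], d_n = d_n, d_c = d_c,
                      dr = computeDR(d_n, d_c))
    attr(out, "shape") <- sh
    out
}

#' Distance ratio of a cytoplasmic position
#'
#' \code{DR = d_n / (d_n + d_c)}: 0 at the nuclear surface, approaching 1 at
#' the cell membrane. The conventional middle/periphery cutoff is DR = 0.909,
#' i.e. \code{d_n / d_c = 10}.
#'
#' @param d_n distance to the nucleus surface (any length unit).
#' @param d_c distance to the cell membrane (same unit). Vectorized.
#' @return DR values in [0, 1]; NA with a warning where d_n + d_c = 0.
#' @examples
#' computeDR(10, 1)   # 0.909...
#' @export
computeDR <- function(d_n, d_c) {
    s <- d_n + d_c
    bad <- !is.na(s) & s == 0
    if (any(bad)) {
        warning("d_n + d_c = 0 for ", sum(bad),
                " position(s); DR set to NA (degenerate geometry)")
        s[bad] <- NA_real_
    }
    d_n / s
}

#' Assign reads to cells and coarse compartments
#'
#' Looks up the cell and nucleus label at each read's voxel. Reads on a
#' nucleus voxel get compartment \code{"nucleus"}; reads on a cytoplasmic
#' voxel get the interim compartment \code{"cytoplasm"} (split into middle/
#' periphery by \code{\link{splitCytoplasm}}); background reads are
#' \code{"unassigned"} with cell_id 0.
#'
#' @param reads a read table with 0-based integer \code{x,y,z} columns.
#' @param seg a \linkS4class{SegmentationSet}.
#' @return the read table with \code{cell_id} and \code{compartment} set.
#' @export
assignReads <- function(reads, seg) {
    sh <- voxelShape(seg)
    if (nrow(reads) == 0L) {
        reads$cell_id <- integer(0); reads$compartment <- character(0)
        return(reads)
    }
    if (any(reads$x < 0 | reads$x >= sh[1L] | reads$y < 0 |
            reads$y >= sh[2L] | reads$z < 0 | reads$z >= sh[3L]))
        stop("read coordinates outside the grid (shape ",
             paste(sh, collapse = " x "), ")")
    idx <- 1L + reads$x + sh[1L] * (reads$y + sh[2L] * reads$z)
    cl <- cellLabels(seg)[idx]
    nl <- nucleusLabels(seg)[idx]
    reads$cell_id <- cl
    reads$compartment <- ifelse(nl > 0L, "nucleus",
                          ifelse(cl > 0L, "cytoplasm", "unassigned"))
    reads
}

#' Split cytoplasmic reads into middle and periphery by DR
#'
#' Joins the per-voxel distance fields onto cytoplasmic reads, stores each
#' read's DR, and relabels the compartment: \code{periphery} when DR is
#' strictly above the cutoff, \code{middle} otherwise (ties go to middle).
#'
#' @param reads a read table with compartments assigned (see
#'   \code{\link{assignReads}}).
#' @param fields output of \code{\link{distanceFields}} on the same grid.
#' @param cutoff DR cutoff in [0, 1); default 0.909 (d_n/d_c = 10).
#' @return the read table with \code{dr} filled and cytoplasmic compartments
#'   set to \code{middle}/\code{periphery}.
#' @export
splitCytoplasm <- function(reads, fields, cutoff = 0.909) {
    if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 ||
        cutoff >= 1)
        stop("'cutoff' must be a single value in [0, 1)")
    if (!"dr" %in% names(reads)) reads$dr <- NA_real_
    cy <- reads$compartment %in% c("cytoplasm", "middle", "periphery")
    if (!any(cy)) return(reads)
    sh <- attr(fields, "shape")
    if (is.null(sh))
        stop("'fields' must come from distanceFields() (missing grid shape)")
    # linear-index join: a voxel belongs to at most one cell
    ridx <- 1L + reads$x + sh[1L] * (reads$y + sh[2L] * reads$z)
    m <- match(ridx[cy], fields$idx)
    if (anyNA(m))
        stop("some cytoplasmic reads have no distance-field entry; ",
             "were the fields computed on the same segmentation?")
    dr <- fields$dr[m]
    reads$dr[cy] <- dr
    reads$compartment[cy] <- ifelse(dr > cutoff, "periphery", "middle")
    reads
}

#' Assign, measure and split in one pass
#'
#' Convenience wrapper running \code{\link{assignReads}},
#' \code{\link{distanceFields}} and \code{\link{splitCytoplasm}}.
#'
#' @inheritParams assignReads
#' @inheritParams splitCytoplasm
#' @param physical measure distances in physical nm (default) or voxel units.
#' @return the fully annotated read table (cell_id, compartment, dr).
#' @export
annotateReads <- function(reads, seg, cutoff = 0.909, physical = TRUE) {
    reads <- assignReads(reads, seg)
    fields <- distanceFields(seg, physical = physical)
    splitCytoplasm(reads, fields, cutoff = cutoff)
}

#' Per-cell voxel volumes
#'
#' Counts nucleus, cytoplasm and total voxels per cell label. The total cell
#' volume (in voxels) is the denominator used to convert counts to
#' concentrations.
#'
#' @param seg a \linkS4class{SegmentationSet}.
#' @param cells optional integer vector of labels to report; absent labels
#'   get zero volumes with a warning.
#' @return data.frame: \code{cell}, \code{nucleus_voxels},
#'   \code{cytoplasm_voxels}, \code{total_voxels}.
#' @export
cellVolumes <- function(seg, cells = NULL) {
    cel <- cellLabels(seg)
    nuc <- nucleusLabels(seg)
    present <- sort(unique(cel[cel > 0L]))
    if (is.null(cells)) cells <- present
    missing <- setdiff(cells, present)
    if (length(missing))
        warning("label(s) ", paste(missing, collapse = ", "),
                " absent from segmentation; volumes reported as 0")
    tot <- tabulate(cel, nbins = max(c(cells, present, 1L)))
    nv <- tabulate(nuc, nbins = max(c(cells, present, 1L)))
    data.frame(cell = cells,
               nucleus_voxels = nv[cells],
               cytoplasm_voxels = tot[cells] - nv[cells],
               total_voxels = tot[cells])
}

#' Compartment read fractions per group of cells
#'
#' Sums reads over genes and cells within each group (by default each chase
#' timepoint) and returns the fraction falling in the nucleus, middle and
#' periphery. Fractions sum to 1 per group.
#'
#' @param cm a \linkS4class{CompartmentMatrix}.
#' @param by name of a colData column to group cells by
#'   (default "timepoint_h").
#' @return data.frame with the grouping value, per-compartment fractions and
#'   the group read total.
#' @export
compartmentFractions <- function(cm, by = "timepoint_h") {
    cd <- colData(cm)
    if (!by %in% names(cd)) stop("no colData column '", by, "'")
    g <- cd[[by]]
    out <- lapply(split(seq_len(ncol(cm)), g), function(sel) {
        tot <- sum(assay(cm, "total")[, sel, drop = FALSE])
        if (tot == 0) stop("empty group in compartmentFractions()")
        c(nucleus = sum(assay(cm, "nucleus")[, sel, drop = FALSE]) / tot,
          middle = sum(assay(cm, "middle")[, sel, drop = FALSE]) / tot,
          periphery = sum(assay(cm, "periphery")[, sel, drop = FALSE]) / tot,
          total_reads = tot)
    })
    res <- data.frame(group = names(out), do.call(rbind, out),
                      row.names = NULL)
    names(res)[1L] <- by
    res
}
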