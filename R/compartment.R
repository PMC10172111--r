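#' Build a CompartmentMatrix from annotated reads
#'
#' Aggregates an annotated read table into sparse gene x cell count matrices
#' per compartment. Because each chase timepoint is a separate (destructively
#' sampled) set of cells, an observed "cell" is the (cell_id, timepoint_h)
#' pair; columns are named \code{c<cell>_t<time>}. Unassigned reads
#' (cell_id 0) are dropped.
#'
#' @param reads annotated read table (see \code{\link{annotateReads}}).
#' @param volumes per-cell volumes: a \linkS4class{SegmentationSet} or the
#'   data.frame returned by \code{\link{cellVolumes}}.
#' @param genes gene universe (default: genes observed in reads); genes with
#'   no reads get zero rows.
#' @return a \linkS4class{CompartmentMatrix}.
#' @export
buildCompartmentMatrix <- function(reads, volumes, genes = NULL) {
    if (is(volumes, "SegmentationSet")) volumes <- cellVolumes(volumes)
    keep <- reads$cell_id > 0L &
        reads$compartment %in% c("nucleus", "middle", "periphery")
    r <- reads[keep, , drop = FALSE]
    if (is.null(genes)) genes <- sort(unique(r$gene))
    cells <- unique(r[, c("cell_id", "timepoint_h")])
    cells <- cells[order(cells$timepoint_h, cells$cell_id), , drop = FALSE]
    ckey <- paste0("c", cells$cell_id, "_t", cells$timepoint_h)
    gi <- match(r$gene, genes)
    ci <- match(paste0("c", r$cell_id, "_t", r$timepoint_h), ckey)
    if (anyNA(gi)) stop("reads contain genes outside the given universe")
    mk <- function(comp) {
        sel <- r$compartment == comp
        Matrix::sparseMatrix(i = gi[sel], j = ci[sel], x = 1,
                             dims = c(length(genes), length(ckey)),
                             dimnames = list(genes, ckey))
    }
    nucM <- mk("nucleus"); midM <- mk("middle"); perM <- mk("periphery")
    vm <- match(cells$cell_id, volumes$cell)
    cd <- S4Vectors::DataFrame(
        cell_id = cells$cell_id, timepoint_h = cells$timepoint_h,
        volume_voxels = volumes$total_voxels[vm],
        nucleus_voxels = volumes$nucleus_voxels[vm],
        phase = NA_character_, row.names = ckey)
    se <- SummarizedExperiment(
        assays = list(nucleus = nucM, middle = midM, periphery = perM,
                      total = nucM + midM + perM),
        colData = cd)
    new("CompartmentMatrix", se)
}

#' Attach cell-cycle phases to a CompartmentMatrix
#'
#' Classifies each observed cell from its (normalized) nascent expression
#' and stores the phase and both scores in colData.
#'
#' @param cm a \linkS4class{CompartmentMatrix}.
#' @param ... passed to \code{\link{classifyCellCycle}}.
#' @return the matrix with colData columns phase, s_g1s, s_g2m filled.
#' @export
addCellCyclePhase <- function(cm, ...) {
    expr <- as.matrix(assay(cm, "total"))
    res <- classifyCellCycle(expr, ...)
    colData(cm)$phase <- res$phase
    colData(cm)$s_g1s <- res$s_g1s
    colData(cm)$s_g2m <- res$s_g2m
    cm
}
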