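#' Cell-cycle marker gene lists
#'
#' The G1/S (19 genes) and G2/M (18 genes) nascent-expression marker panels
#' used for cell-cycle phase classification.
#'
#' @return character vector of gene symbols.
#' @export
g1sMarkers <- function() {
    c("BCL2L1", "CDC6", "DSCC1", "DTL", "MCM5", "UNG", "SNN", "FEN1",
      "GINS2", "GMNN", "MCM2", "MCM4", "MCM6", "PCNA", "PRIM1", "RRM1",
      "TYMS", "UHRF1", "CDCA7")
}

#' @rdname g1sMarkers
#' @export
g2mMarkers <- function() {
    c("TOP2A", "TPX2", "UBE2C", "HJURP", "BIRC5", "CCNB2", "CDCA2",
      "CKAP5", "CKS1B", "CKS2", "HMGB2", "NCAPD2", "NDC80", "NUF2",
      "TACC3", "TMPO", "MKI67", "CENPF")
}

#' Score a gene set against an expression-matched control pool
#'
#' Computes, per cell, the mean expression of the set genes minus the mean
#' expression of a control pool: genes are binned by average expression into
#' \code{nBins} equal-size bins and \code{nCtrl} control genes are sampled
#' (seeded) from each set gene's bin, excluding the set itself. The control
#' draws are kept per set gene (a control picked for several set genes
#' counts once per pick), so the pool's bin composition mirrors the set's
#' and the score is centered at 0 for sets that behave like the background,
#' regardless of expression level.
#'
#' @param expr normalized gene x cell matrix.
#' @param genes gene-set names (at least one must be present in expr).
#' @param nBins number of expression bins (default 25).
#' @param nCtrl controls sampled per set gene (default 50); capped at the
#'   bin content.
#' @param seed RNG seed for the control draw.
#' @return numeric per-cell score, named by column.
#' @export
scoreGeneSet <- function(expr, genes, nBins = 25L, nCtrl = 50L, seed = 1L) {
    genes <- intersect(genes, rownames(expr))
    if (length(genes) == 0L)
        stop("no gene-set members present in the expression matrix")
    set.seed(seed)
    avg <- rowMeans(expr)
    nBins <- min(nBins, nrow(expr))
    bin <- if (nBins == 1L) rep(1L, nrow(expr)) else
        cut(rank(avg, ties.method = "first"), breaks = nBins, labels = FALSE)
    names(bin) <- rownames(expr)
    ctrl <- character(0)
    for (g in genes) {
        pool <- setdiff(names(bin)[bin == bin[[g]]], genes)
        if (length(pool) == 0L) next
        ctrl <- c(ctrl, sample(pool, min(nCtrl, length(pool))))
    }
    if (length(ctrl) == 0L)
        stop("empty control pool; too few background genes")
    colMeans(expr[genes, , drop = FALSE]) -
        colMeans(expr[ctrl, , drop = FALSE])
}

#' Assign cell-cycle phases from G1/S and G2/M scores
#'
#' A cell is G1 when both scores are nonpositive; otherwise it takes the
#' phase of the larger score. Exact ties between positive scores go to G2/M
#' with a warning.
#'
#' @param sG1S,sG2M per-cell gene-set scores.
#' @return character vector of phases in \{"G1", "G1/S", "G2/M"\}.
#' @export
assignPhase <- function(sG1S, sG2M) {
    stopifnot(length(sG1S) == length(sG2M))
    phase <- rep("G1", length(sG1S))
    pos <- sG1S > 0 | sG2M > 0
    tie <- pos & sG1S == sG2M
    if (any(tie))
        warning(sum(tie), " cell(s) with tied phase scores assigned to G2/M")
    phase[pos] <- ifelse(sG1S[pos] > sG2M[pos], "G1/S", "G2/M")
    phase
}

#' Classify cells into cell-cycle phases
#'
#' Scores the G1/S and G2/M marker panels on nascent expression and assigns
#' each cell a phase.
#'
#' @inheritParams scoreGeneSet
#' @param g1s,g2m marker panels (defaults: \code{\link{g1sMarkers}},
#'   \code{\link{g2mMarkers}}).
#' @return data.frame: cell, s_g1s, s_g2m, phase.
#' @export
classifyCellCycle <- function(expr, g1s = g1sMarkers(), g2m = g2mMarkers(),
                              nBins = 25L, nCtrl = 50L, seed = 1L) {
    s1 <- scoreGeneSet(expr, g1s, nBins = nBins, nCtrl = nCtrl, seed = seed)
    s2 <- scoreGeneSet(expr, g2m, nBins = nBins, nCtrl = nCtrl,
                       seed = seed + 1L)
    data.frame(cell = colnames(expr), s_g1s = as.numeric(s1),
               s_g2m = as.numeric(s2), phase = assignPhase(s1, s2),
               stringsAsFactors = FALSE)
}
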