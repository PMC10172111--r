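#' Assemble a gene x parameter matrix from kinetic estimates
#'
#' Pivots a kinetic estimate table (see \code{\link{estimateAll}}) into a
#' genes x parameters matrix: 4 columns for pooled estimates or 4 x phases
#' columns (named e.g. \code{alpha.G1}) for phase-resolved estimates. Genes
#' with any missing value are dropped with a message. Only QC-passing rows
#' are kept when \code{qcOnly = TRUE}: phase-resolved genes must pass QC in
#' every phase.
#'
#' @param estimates data.frame from \code{\link{estimateAll}}.
#' @param parameters which parameters to include.
#' @param qcOnly keep only genes passing QC (in all phases).
#' @return numeric matrix, rownames = genes.
#' @export
parameterMatrix <- function(estimates,
                            parameters = c("alpha", "beta", "lam", "gamma"),
                            qcOnly = TRUE) {
    if (qcOnly) {
        ok <- tapply(estimates$qc_pass, estimates$gene, all)
        estimates <- estimates[estimates$gene %in% names(ok)[ok], ,
                               drop = FALSE]
    }
    phases <- sort(unique(estimates$phase))
    genes <- sort(unique(estimates$gene))
    cols <- if (length(phases) == 1L) parameters else
        as.vector(outer(parameters, phases, paste, sep = "."))
    m <- matrix(NA_real_, length(genes), length(cols),
                dimnames = list(genes, cols))
    for (p in phases) {
        sub <- estimates[estimates$phase == p, , drop = FALSE]
        ri <- match(sub$gene, genes)
        for (par in parameters) {
            cn <- if (length(phases) == 1L) par else paste(par, p, sep = ".")
            m[ri, cn] <- sub[[par]]
        }
    }
    drop <- !complete.cases(m)
    if (any(drop)) {
        message("dropping ", sum(drop), " gene(s) with missing parameters")
        m <- m[!drop, , drop = FALSE]
    }
    m
}

#' Standardize parameters column-wise (z-scores)
#'
#' Centers each parameter and scales by the sample (n-1) standard deviation,
#' so that clustering sees each kinetic constant on a comparable scale.
#'
#' @param pm genes x parameters matrix.
#' @return matrix of the same shape with column mean 0 and sd 1.
#' @export
zscoreParameters <- function(pm) {
    sds <- apply(pm, 2L, sd)
    if (any(sds == 0))
        stop("zero-variance parameter column(s): ",
             paste(colnames(pm)[sds == 0], collapse = ", "))
    scale(pm)[, , drop = FALSE]
}

#' Pairwise Pearson correlation of kinetic parameters
#'
#' @param pm genes x parameters matrix (at least 3 complete rows).
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   columns yield NA entries with a warning.
#' @export
pairwiseParameterCorrelation <- function(pm) {
    pm <- pm[complete.cases(pm), , drop = FALSE]
    if (nrow(pm) < 3L) stop("need at least 3 complete gene rows")
    sds <- apply(pm, 2L, sd)
    if (any(sds == 0))
        warning("zero-variance column(s) produce NA correlations: ",
                paste(colnames(pm)[sds == 0], collapse = ", "))
    r <- suppressWarnings(cor(pm))
    diag(r) <- ifelse(sds == 0, NA_real_, 1)
    r
}

#' Cluster genes on z-scored kinetic parameters
#'
#' Builds a k-nearest-neighbor graph on the Euclidean distances between
#' z-scored parameter rows (edges are the union of directed kNN relations)
#' and partitions it with Louvain community detection at the given
#' resolution. Labels are deterministic given the seed.
#'
#' @param z genes x parameters z-score matrix (see
#'   \code{\link{zscoreParameters}}).
#' @param kNeighbors neighbors per gene (default 20; must be < nrow(z)).
#' @param resolution Louvain resolution (default 1.0).
#' @param seed RNG seed.
#' @return named integer cluster labels (1-based), one per gene.
#' @export
clusterKinetics <- function(z, kNeighbors = 20L, resolution = 1.0,
                            seed = 1L) {
    n <- nrow(z)
    if (kNeighbors >= n) stop("'kNeighbors' must be smaller than nrow(z)")
    d <- as.matrix(stats::dist(z))
    if (max(d) == 0)   # all rows identical: one trivial community
        return(setNames(rep(1L, n), rownames(z)))
    edges <- lapply(seq_len(n), function(i) {
        o <- order(d[i, ])
        nb <- o[o != i][seq_len(kNeighbors)]
        cbind(i, nb)
    })
    e <- unique(t(apply(do.call(rbind, edges), 1L, sort)))
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    if (igraph::vcount(g) < n)
        g <- igraph::add_vertices(g, n - igraph::vcount(g))
    deg0 <- igraph::degree(g) == 0
    if (any(deg0))
        warning(sum(deg0), " singleton gene(s) in the kNN graph")
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    setNames(as.integer(igraph::membership(cl)), rownames(z))
}

#' Gene-gene expression covariation across and within timepoints
#'
#' Computes the Pearson correlation of per-cell expression between every
#' gene pair using all cells pooled over the given timepoints, orders genes
#' by average-linkage hierarchical clustering on the correlation distance
#' (1 - r), and returns per-timepoint correlation matrices that reuse
#' exactly that combined ordering so covariation patterns can be compared
#' over time.
#'
#' @param exprByTime named list of gene x cell matrices, one per timepoint
#'   (names are the timepoints, in order); at least 3 cells each.
#' @return list: \code{combined} (ordered correlation matrix),
#'   \code{perTimepoint} (list of matrices in the same order), \code{order}
#'   (the gene ordering used). Zero-variance genes get NA rows/columns with
#'   a warning.
#' @export
covariationOverTime <- function(exprByTime) {
    stopifnot(is.list(exprByTime), length(exprByTime) >= 1L)
    genes <- rownames(exprByTime[[1L]])
    for (m in exprByTime) {
        if (!identical(rownames(m), genes))
            stop("all matrices must share one gene ordering")
        if (ncol(m) < 3L) stop("need >= 3 cells per timepoint")
    }
    all <- do.call(cbind, exprByTime)
    v <- apply(all, 1L, var)
    if (any(v == 0))
        warning("zero-variance gene(s) set to NA: ",
                paste(genes[v == 0], collapse = ", "))
    combined <- suppressWarnings(cor(t(all)))
    usable <- v > 0
    hc <- hclust(as.dist(1 - combined[usable, usable]), method = "average")
    ord <- c(genes[usable][hc$order], genes[!usable])
    combined <- combined[ord, ord]
    per <- lapply(exprByTime, function(m)
        suppressWarnings(cor(t(m)))[ord, ord])
    list(combined = combined, perTimepoint = per, order = ord)
}

#' Concatenate nuclear and cytoplasmic expression per cell
#'
#' Builds the cell x 2G nucleocytoplasmic matrix: for every gene one
#' \code{_nuc} column (nucleus counts) and one \code{_cyto} column (middle +
#' periphery counts). Row sums equal each cell's total read count, so the
#' concatenation is a lossless re-arrangement of the compartment counts.
#'
#' @param cm a \linkS4class{CompartmentMatrix}.
#' @return sparse cell x (2 x genes) matrix.
#' @export
buildNucleocytoplasmicMatrix <- function(cm) {
    nucT <- Matrix::t(assay(cm, "nucleus"))
    cytT <- Matrix::t(assay(cm, "middle") + assay(cm, "periphery"))
    colnames(nucT) <- paste0(rownames(cm), "_nuc")
    colnames(cytT) <- paste0(rownames(cm), "_cyto")
    cbind(nucT, cytT)
}

#' Compare a kinetic parameter between two gene groups
#'
#' Two-sided Wilcoxon rank-sum test of a parameter between gene groups (for
#' example m6A-modified vs unmodified transcripts). Exact p-values are used
#' for small tie-free groups, the normal approximation with tie correction
#' otherwise (the default behavior of \code{\link[stats]{wilcox.test}}).
#' Only QC-passing estimates enter the test.
#'
#' @param estimates data.frame from \code{\link{estimateAll}}.
#' @param labels named character vector, gene -> group label (genes labeled
#'   "unknown" or absent are ignored).
#' @param parameter which column to test (e.g. "beta").
#' @param groups character(2), the two labels to compare.
#' @return list: statistic (W), p.value, medians (per group), n (per group).
#' @export
compareGeneGroups <- function(estimates, labels, parameter = "beta",
                              groups = c("m6a", "non_m6a")) {
    est <- estimates[estimates$qc_pass, , drop = FALSE]
    lab <- labels[est$gene]
    x <- est[[parameter]][!is.na(lab) & lab == groups[1L]]
    y <- est[[parameter]][!is.na(lab) & lab == groups[2L]]
    if (length(x) == 0L || length(y) == 0L)
        stop("one of the groups is empty after QC filtering")
    wt <- wilcox.test(x, y, alternative = "two.sided")
    list(statistic = unname(wt$statistic), p.value = wt$p.value,
         medians = setNames(c(median(x), median(y)), groups),
         n = setNames(c(length(x), length(y)), groups))
}
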