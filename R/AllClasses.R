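#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData assay<- colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' VoxelGrid: an anisotropic 3D voxel lattice
#'
#' Describes the imaging lattice on which label volumes and read coordinates
#' live: the number of voxels along x, y, z and the physical voxel pitch in
#' nanometres. The default pitch (200, 200, 350 nm) is the confocal sampling
#' used for HeLa-scale cultured cells.
#'
#' @slot shape integer(3), voxel counts along (x, y, z); all > 0.
#' @slot spacing numeric(3), voxel pitch in nm along (x, y, z); all > 0.
#' @export
setClass("VoxelGrid", representation(shape = "integer", spacing = "numeric"))

setValidity("VoxelGrid", function(object) {
    if (length(object@shape) != 3L || any(is.na(object@shape)) ||
        any(object@shape <= 0L))
        return("'shape' must be 3 positive integers")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        return("'spacing' must be 3 positive lengths (nm)")
    TRUE
})

#' Construct a VoxelGrid
#'
#' @param shape voxel counts along (x, y, z).
#' @param spacing voxel pitch in nm along (x, y, z). Default 200 x 200 x 350.
#' @return A \linkS4class{VoxelGrid}.
#' @examples
#' VoxelGrid(c(64, 64, 16))
#' @export
VoxelGrid <- function(shape, spacing = c(200, 200, 350)) {
    new("VoxelGrid", shape = as.integer(shape), spacing = as.numeric(spacing))
}

#' SegmentationSet: paired nucleus/cell 3D label volumes
#'
#' Holds the nucleus and whole-cell label volumes on a shared
#' \linkS4class{VoxelGrid}. Voxels are labeled by cell id (1..n, 0 =
#' background); every nucleus voxel of cell k must also carry cell label k,
#' so the cytoplasm of cell k is its cell voxels minus its nucleus voxels.
#'
#' @slot grid a \linkS4class{VoxelGrid}.
#' @slot nucleusLabels integer 3D array, dim = grid shape.
#' @slot cellLabels integer 3D array, dim = grid shape.
#' @export
setClass("SegmentationSet",
    representation(grid = "VoxelGrid", nucleusLabels = "array",
                   cellLabels = "array"))

setValidity("SegmentationSet", function(object) {
    sh <- object@grid@shape
    if (!identical(dim(object@nucleusLabels), as.integer(sh)) ||
        !identical(dim(object@cellLabels), as.integer(sh)))
        return("label volumes must have dim equal to the grid shape")
    nuc <- object@nucleusLabels
    cel <- object@cellLabels
    inn <- nuc > 0L
    if (any(cel[inn] != nuc[inn]))
        return("nucleus voxels must carry the same cell label in 'cellLabels'")
    TRUE
})

#' Construct a SegmentationSet
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param nucleusLabels,cellLabels integer 3D label arrays (0 = background).
#' @return A \linkS4class{SegmentationSet}.
#' @export
SegmentationSet <- function(grid, nucleusLabels, cellLabels) {
    storage.mode(nucleusLabels) <- "integer"
    storage.mode(cellLabels) <- "integer"
    new("SegmentationSet", grid = grid, nucleusLabels = nucleusLabels,
        cellLabels = cellLabels)
}

#' PulseChaseDesign: the labeling schedule
#'
#' Records the pulse duration, the ordered chase times, and which chase
#' times are excluded from kinetic regressions. The default exclusion is the
#' 1 h chase sample, where residual label during the chase can inflate
#' apparent abundance; at least 3 non-excluded chase times are required for
#' the regression stages. An optional long-pulse steady-state sample is
#' carried separately (encoded as timepoint -1 in read tables) so it can
#' never silently enter a kinetic fit.
#'
#' @slot pulseHours numeric(1), pulse duration in h.
#' @slot chaseHours numeric, strictly increasing nonnegative chase times (h).
#' @slot excludedChaseHours numeric, subset of \code{chaseHours} excluded
#'   from regressions.
#' @slot steadyStateHours numeric(1) or NA, duration of an optional
#'   long-pulse steady-state sample.
#' @export
setClass("PulseChaseDesign",
    representation(pulseHours = "numeric", chaseHours = "numeric",
                   excludedChaseHours = "numeric",
                   steadyStateHours = "numeric"))

setValidity("PulseChaseDesign", function(object) {
    ch <- object@chaseHours
    if (length(ch) < 1L || any(ch < 0) || is.unsorted(ch, strictly = TRUE))
        return("'chaseHours' must be strictly increasing and nonnegative")
    if (length(object@pulseHours) != 1L || object@pulseHours <= 0)
        return("'pulseHours' must be a single positive duration")
    if (!all(object@excludedChaseHours %in% ch))
        return("'excludedChaseHours' must be a subset of 'chaseHours'")
    if (length(setdiff(ch, object@excludedChaseHours)) < 3L)
        return("need >= 3 non-excluded chase timepoints for regression stages")
    TRUE
})

#' Construct a PulseChaseDesign
#'
#' @param pulseHours pulse duration in h (default 1).
#' @param chaseHours chase times in h (default c(0, 1, 2, 4, 6)).
#' @param excludedChaseHours chase times excluded from kinetic fits
#'   (default 1).
#' @param steadyStateHours optional long-pulse duration (h), NA if absent.
#' @return A \linkS4class{PulseChaseDesign}.
#' @examples
#' PulseChaseDesign()
#' @export
PulseChaseDesign <- function(pulseHours = 1, chaseHours = c(0, 1, 2, 4, 6),
                             excludedChaseHours = 1,
                             steadyStateHours = NA_real_) {
    new("PulseChaseDesign", pulseHours = as.numeric(pulseHours),
        chaseHours = as.numeric(chaseHours),
        excludedChaseHours = as.numeric(excludedChaseHours),
        steadyStateHours = as.numeric(steadyStateHours))
}

#' Codebook: two-base color-space barcode dictionary
#'
#' Maps genes to DNA barcodes and to their expected color sequences under
#' two-base (dinucleotide) encoding. A 5-nt barcode flanked by one anchor
#' base on each side yields 6 overlapping dinucleotides, hence 6 color
#' rounds. Color sequences must be unique across genes; a collision is a
#' construction error, not a runtime rejection.
#'
#' @slot genes character, gene names.
#' @slot barcodes character, DNA barcodes over {A,C,G,T}, one per gene.
#' @slot colors integer matrix, genes x rounds, values in 0..3.
#' @slot colorMap named integer vector, 16 dinucleotides -> 0..3.
#' @slot anchors character(2), 5' and 3' anchor bases.
#' @export
setClass("Codebook",
    representation(genes = "character", barcodes = "character",
                   colors = "matrix", colorMap = "integer",
                   anchors = "character"))

setValidity("Codebook", function(object) {
    if (length(object@genes) != length(object@barcodes) ||
        length(object@genes) != nrow(object@colors))
        return("genes, barcodes and color rows must align")
    if (anyDuplicated(object@genes))
        return("duplicated gene names in codebook")
    key <- apply(object@colors, 1L, paste, collapse = "")
    if (anyDuplicated(key)) {
        dup <- object@genes[duplicated(key) | duplicated(key, fromLast = TRUE)]
        return(paste0("color-sequence collision among genes: ",
                      paste(unique(dup), collapse = ", ")))
    }
    if (!all(grepl("^[ACGT]+$", object@barcodes)))
        return("barcodes must be over {A,C,G,T}")
    TRUE
})

#' SimConfig: configuration for the pulse-chase simulator
#'
#' @slot nCells integer(1), number of cells in the geometry.
#' @slot geneTruth data.frame of per-gene ground-truth parameters (see
#'   \code{\link{geneTruthTable}}).
#' @slot pulseHours,chaseHours pulse duration and chase times (h).
#' @slot detectionEfficiency probability in (0, 1] that a surviving molecule
#'   is detected at a sampled timepoint.
#' @slot exportMode "first_order_hazard" or "linear_fraction_schedule".
#' @slot translocationMode "dr_drift" or "none".
#' @slot phaseFractions numeric(3), P(G1), P(G1/S), P(G2/M); sums to 1.
#' @slot seed integer(1), RNG seed; identical config + seed gives a
#'   byte-identical read table.
#' @export
setClass("SimConfig",
    representation(nCells = "integer", geneTruth = "data.frame",
                   pulseHours = "numeric", chaseHours = "numeric",
                   detectionEfficiency = "numeric", exportMode = "character",
                   translocationMode = "character",
                   phaseFractions = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    if (object@nCells < 0L) return("'nCells' must be >= 0")
    de <- object@detectionEfficiency
    if (length(de) != 1L || de <= 0 || de > 1)
        return("'detectionEfficiency' must be in (0, 1]")
    ch <- object@chaseHours
    if (any(ch < 0) || is.unsorted(ch, strictly = TRUE))
        return("'chaseHours' must be strictly increasing and nonnegative")
    if (!object@exportMode %in%
        c("first_order_hazard", "linear_fraction_schedule"))
        return("invalid 'exportMode'")
    if (!object@translocationMode %in% c("dr_drift", "none"))
        return("invalid 'translocationMode'")
    pf <- object@phaseFractions
    if (length(pf) != 3L || any(pf < 0) || abs(sum(pf) - 1) > 1e-9)
        return("'phaseFractions' must be 3 probabilities summing to 1")
    gt <- object@geneTruth
    need <- c("gene", "alpha", "beta", "lam", "gamma", "is_reference")
    if (!all(need %in% names(gt)))
        return(paste("geneTruth must contain columns:",
                     paste(need, collapse = ", ")))
    if (any(gt$alpha < 0) || any(gt$beta < 0))
        return("alpha and beta must be >= 0")
    if (any(gt$is_reference & gt$beta != 0))
        return("reference genes must have beta = 0")
    TRUE
})

#' CompartmentMatrix: compartment-resolved gene x cell counts
#'
#' A \linkS4class{SummarizedExperiment} with four assays — \code{nucleus},
#' \code{middle}, \code{periphery} and \code{total} — holding sparse gene x
#' cell count matrices. The three compartment assays sum to \code{total}
#' elementwise. Column (cell) metadata carries \code{cell_id},
#' \code{timepoint_h}, \code{volume_voxels} (total cell voxels),
#' \code{nucleus_voxels} and, once assigned, \code{phase}.
#'
#' @export
setClass("CompartmentMatrix", contains = "SummarizedExperiment")

setValidity("CompartmentMatrix", function(object) {
    an <- assayNames(object)
    need <- c("nucleus", "middle", "periphery", "total")
    if (!all(need %in% an))
        return(paste("assays must include:", paste(need, collapse = ", ")))
    s <- assay(object, "nucleus") + assay(object, "middle") +
        assay(object, "periphery")
    if (max(abs(s - assay(object, "total"))) > 1e-6)
        return("nucleus + middle + periphery must equal total elementwise")
    if (min(assay(object, "total")) < 0)
        return("counts must be nonnegative")
    cd <- colData(object)
    need <- c("cell_id", "timepoint_h", "volume_voxels")
    if (!all(need %in% names(cd)))
        return(paste("colData must include:", paste(need, collapse = ", ")))
    TRUE
})

setMethod("show", "VoxelGrid", function(object) {
    cat("VoxelGrid:", paste(object@shape, collapse = " x "), "voxels,",
        paste(object@spacing, collapse = " x "), "nm\n")
})

setMethod("show", "SegmentationSet", function(object) {
    n <- max(object@cellLabels)
    cat("SegmentationSet:", n, "cell(s) on a",
        paste(object@grid@shape, collapse = " x "), "grid\n")
})

setMethod("show", "PulseChaseDesign", function(object) {
    cat("PulseChaseDesign:", object@pulseHours, "h pulse; chase {",
        paste(object@chaseHours, collapse = ", "), "} h; excluded {",
        paste(object@excludedChaseHours, collapse = ", "), "} h\n")
})

setMethod("show", "Codebook", function(object) {
    cat("Codebook:", length(object@genes), "genes,",
        ncol(object@colors), "color rounds, anchors",
        paste(object@anchors, collapse = "/"), "\n")
})
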