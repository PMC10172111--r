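#' @importFrom utils read.delim write.table
NULL

.READ_COLS <- c("gene", "x", "y", "z", "timepoint_h", "cell_id",
                "compartment", "dr", "quality")

#' Read and write read tables as TSV
#'
#' The read-table schema has one row per decoded molecule: gene, 0-based
#' voxel coordinates x/y/z, chase time in h (-1 encodes a long-pulse
#' steady-state sample), cell_id (0 = unassigned), compartment (nucleus /
#' middle / periphery / cytoplasm / unassigned), dr and quality (NA where
#' not applicable). Unknown extra columns are preserved. Writing sorts rows
#' by (timepoint, cell, gene, x, y, z) so outputs are deterministic and
#' diffable; a write/read round trip is the identity on schema columns.
#'
#' @param reads a read table.
#' @param path file path.
#' @param design optional \linkS4class{PulseChaseDesign}; when given,
#'   timepoints outside the design (other than -1) raise an error naming the
#'   offending row.
#' @return \code{readReadsTSV}: the read table; \code{writeReadsTSV}:
#'   invisibly, the path.
#' @export
writeReadsTSV <- function(reads, path) {
    o <- order(reads$timepoint_h, reads$cell_id, reads$gene, reads$x,
               reads$y, reads$z)
    write.table(reads[o, , drop = FALSE], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeReadsTSV
#' @export
readReadsTSV <- function(path, design = NULL) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    miss <- setdiff(.READ_COLS, names(df))
    if (length(miss))
        stop("missing required column(s): ", paste(miss, collapse = ", "))
    for (cc in c("x", "y", "z", "cell_id")) {
        if (nrow(df) && any(df[[cc]] != as.integer(df[[cc]])))
            stop("non-integer values in column '", cc, "'")
        df[[cc]] <- as.integer(df[[cc]])
    }
    for (cc in c("dr", "quality", "timepoint_h"))
        df[[cc]] <- as.numeric(df[[cc]])
    if (!is.null(design) && nrow(df)) {
        ok <- df$timepoint_h %in% c(design@chaseHours, -1)
        if (!all(ok))
            stop("timepoint ", df$timepoint_h[which(!ok)[1L]],
                 " (row ", which(!ok)[1L], ") is not in the design")
    }
    df
}

#' Write and read 3D label volumes as multi-page TIFF
#'
#' One 16-bit page per z-plane (rows = y, cols = x), with a JSON sidecar
#' recording the grid shape, voxel spacing in nm and the axis order, since
#' TIFF itself does not carry anisotropic spacing.
#'
#' @param vol integer 3D array (x, y, z), labels in 0..65535.
#' @param path TIFF path.
#' @param spacing voxel spacing in nm.
#' @param sidecar JSON sidecar path (default \code{<path>.json}).
#' @return \code{readLabelTIFF}: list with \code{volume} (integer array) and
#'   \code{spacing}.
#' @export
writeLabelTIFF <- function(vol, path, spacing = c(200, 200, 350),
                           sidecar = paste0(path, ".json")) {
    if (max(vol) > 65535L) stop("labels exceed 16-bit range")
    if (max(vol) == 0L) warning("no labels in volume")
    pages <- lapply(seq_len(dim(vol)[3L]),
                    function(z) t(vol[, , z]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                    compression = "none")
    jsonlite::write_json(
        list(shape = dim(vol), spacing_nm = spacing,
             axis_order = "page=z,row=y,col=x"),
        sidecar, auto_unbox = FALSE, digits = NA)
    invisible(path)
}

#' @rdname writeLabelTIFF
#' @export
readLabelTIFF <- function(path, sidecar = paste0(path, ".json")) {
    if (!file.exists(sidecar))
        stop("missing sidecar '", sidecar, "' (voxel spacing unknown)")
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    dims <- unique(lapply(pages, dim))
    if (length(dims) != 1L) stop("ragged TIFF pages (unequal dimensions)")
    vol <- array(0L, dim = c(dims[[1L]][2L], dims[[1L]][1L], length(pages)))
    for (z in seq_along(pages))
        vol[, , z] <- as.integer(round(t(pages[[z]]) * 65535))
    if (max(vol) == 0L) warning("no labels in volume")
    list(volume = vol, spacing = as.numeric(meta$spacing_nm))
}

#' Write and read a SegmentationSet as TIFF pairs
#'
#' @param seg a \linkS4class{SegmentationSet}.
#' @param dir output directory (created if needed); files are
#'   \code{labels_nucleus.tif}, \code{labels_cell.tif} and
#'   \code{geometry.json}.
#' @return \code{readSegmentation}: the \linkS4class{SegmentationSet}.
#' @export
writeSegmentation <- function(seg, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    side <- file.path(dir, "geometry.json")
    writeLabelTIFF(nucleusLabels(seg), file.path(dir, "labels_nucleus.tif"),
                   spacing = voxelSpacing(seg), sidecar = side)
    writeLabelTIFF(cellLabels(seg), file.path(dir, "labels_cell.tif"),
                   spacing = voxelSpacing(seg), sidecar = side)
    invisible(dir)
}

#' @rdname writeSegmentation
#' @export
readSegmentation <- function(dir) {
    side <- file.path(dir, "geometry.json")
    nuc <- readLabelTIFF(file.path(dir, "labels_nucleus.tif"), side)
    cel <- readLabelTIFF(file.path(dir, "labels_cell.tif"), side)
    SegmentationSet(VoxelGrid(dim(nuc$volume), nuc$spacing),
                    nuc$volume, cel$volume)
}

#' Write and read a CompartmentMatrix in Matrix Market format
#'
#' Each assay becomes \code{counts_<assay>.mtx} in coordinate format, with
#' \code{genes.tsv} and \code{cells.tsv} sidecars (the standard interchange
#' layout for gene x cell matrices).
#'
#' @param cm a \linkS4class{CompartmentMatrix}.
#' @param dir output directory.
#' @return \code{readCompartmentMatrix}: the matrix.
#' @export
writeCompartmentMatrix <- function(cm, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (a in c("nucleus", "middle", "periphery", "total"))
        Matrix::writeMM(as(as(assay(cm, a), "dMatrix") * 1, "CsparseMatrix"),
                        file.path(dir, paste0("counts_", a, ".mtx")))
    write.table(data.frame(gene = rownames(cm)),
                file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cd <- as.data.frame(colData(cm))
    cd <- cbind(cell = rownames(cd), cd)
    write.table(cd, file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(dir)
}

#' @rdname writeCompartmentMatrix
#' @export
readCompartmentMatrix <- function(dir) {
    genes <- read.delim(file.path(dir, "genes.tsv"))$gene
    cd <- read.delim(file.path(dir, "cells.tsv"))
    rn <- cd$cell
    cd$cell <- NULL
    assays <- lapply(c("nucleus", "middle", "periphery", "total"),
                     function(a) {
        m <- Matrix::readMM(file.path(dir, paste0("counts_", a, ".mtx")))
        m <- as(m, "dMatrix") * 1   # pattern/logical files become numeric
        dimnames(m) <- list(genes, rn)
        as(m, "CsparseMatrix")
    })
    names(assays) <- c("nucleus", "middle", "periphery", "total")
    se <- SummarizedExperiment(assays = assays,
                               colData = S4Vectors::DataFrame(cd,
                                                              row.names = rn))
    new("CompartmentMatrix", se)
}

#' Read and write gene-set annotations (YAML)
#'
#' The gene-sets file carries the reference (control) genes, the G1/S and
#' G2/M cell-cycle marker panels, and an optional gene -> m6A label map
#' (values m6a / non_m6a / unknown). Marker lists must be disjoint.
#'
#' @param path YAML file.
#' @return list: reference_genes, g1s_markers, g2m_markers, m6a_labels
#'   (named character vector or NULL).
#' @export
readGeneSets <- function(path) {
    gs <- yaml::read_yaml(path)
    g1s <- unlist(gs$g1s_markers); g2m <- unlist(gs$g2m_markers)
    if (length(intersect(g1s, g2m)))
        stop("marker lists overlap: ",
             paste(intersect(g1s, g2m), collapse = ", "))
    m6a <- NULL
    if (!is.null(gs$m6a_labels)) m6a <- unlist(gs$m6a_labels)
    list(reference_genes = unlist(gs$reference_genes), g1s_markers = g1s,
         g2m_markers = g2m, m6a_labels = m6a)
}

#' @rdname readGeneSets
#' @param genesets a list as returned by \code{readGeneSets}.
#' @export
writeGeneSets <- function(genesets, path) {
    yaml::write_yaml(lapply(genesets, as.list), path)
    invisible(path)
}

#' Read and write a pulse-chase design (YAML)
#'
#' @param path YAML file with pulse_hours, chase_hours,
#'   excluded_chase_hours, steady_state_hours.
#' @return \code{readDesign}: a \linkS4class{PulseChaseDesign}.
#' @export
readDesign <- function(path) {
    d <- yaml::read_yaml(path)
    PulseChaseDesign(
        pulseHours = d$pulse_hours,
        chaseHours = unlist(d$chase_hours),
        excludedChaseHours = if (is.null(d$excluded_chase_hours)) numeric(0)
                             else unlist(d$excluded_chase_hours),
        steadyStateHours = if (is.null(d$steady_state_hours)) NA_real_
                           else d$steady_state_hours)
}

#' @rdname readDesign
#' @param design a \linkS4class{PulseChaseDesign}.
#' @export
writeDesign <- function(design, path) {
    yaml::write_yaml(list(
        pulse_hours = design@pulseHours,
        chase_hours = as.list(design@chaseHours),
        excluded_chase_hours = as.list(design@excludedChaseHours),
        steady_state_hours = if (is.na(design@steadyStateHours)) NULL
                             else design@steadyStateHours), path)
    invisible(path)
}
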