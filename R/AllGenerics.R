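#' Accessors for grid and segmentation objects
#'
#' \code{voxelShape} and \code{voxelSpacing} return the lattice dimensions
#' and physical pitch (nm); \code{nucleusLabels} and \code{cellLabels} return
#' the 3D label arrays; \code{segGrid} returns the underlying
#' \linkS4class{VoxelGrid}.
#'
#' @param x a \linkS4class{VoxelGrid} or \linkS4class{SegmentationSet}.
#' @return The requested component.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("voxelShape", function(x) standardGeneric("voxelShape"))
#' @rdname grid-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname grid-accessors
#' @export
setGeneric("nucleusLabels", function(x) standardGeneric("nucleusLabels"))
#' @rdname grid-accessors
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))
#' @rdname grid-accessors
#' @export
setGeneric("segGrid", function(x) standardGeneric("segGrid"))

#' @rdname grid-accessors
setMethod("voxelShape", "VoxelGrid", function(x) x@shape)
#' @rdname grid-accessors
setMethod("voxelSpacing", "VoxelGrid", function(x) x@spacing)
#' @rdname grid-accessors
setMethod("voxelShape", "SegmentationSet", function(x) x@grid@shape)
#' @rdname grid-accessors
setMethod("voxelSpacing", "SegmentationSet", function(x) x@grid@spacing)
#' @rdname grid-accessors
setMethod("nucleusLabels", "SegmentationSet", function(x) x@nucleusLabels)
#' @rdname grid-accessors
setMethod("cellLabels", "SegmentationSet", function(x) x@cellLabels)
#' @rdname grid-accessors
setMethod("segGrid", "SegmentationSet", function(x) x@grid)

#' Accessors for Codebook objects
#'
#' @param x a \linkS4class{Codebook}.
#' @return \code{cbGenes}: gene names; \code{cbBarcodes}: DNA barcodes;
#'   \code{cbColors}: the genes x rounds color matrix; \code{nRounds}: the
#'   number of color rounds.
#' @name codebook-accessors
NULL

#' @rdname codebook-accessors
#' @export
setGeneric("cbGenes", function(x) standardGeneric("cbGenes"))
#' @rdname codebook-accessors
#' @export
setGeneric("cbBarcodes", function(x) standardGeneric("cbBarcodes"))
#' @rdname codebook-accessors
#' @export
setGeneric("cbColors", function(x) standardGeneric("cbColors"))
#' @rdname codebook-accessors
#' @export
setGeneric("nRounds", function(x) standardGeneric("nRounds"))

#' @rdname codebook-accessors
setMethod("cbGenes", "Codebook", function(x) x@genes)
#' @rdname codebook-accessors
setMethod("cbBarcodes", "Codebook", function(x) x@barcodes)
#' @rdname codebook-accessors
setMethod("cbColors", "Codebook", function(x) x@colors)
#' @rdname codebook-accessors
setMethod("nRounds", "Codebook", function(x) ncol(x@colors))
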