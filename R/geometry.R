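#' Generate a synthetic nucleus/cell segmentation
#'
#' Places \code{nCells} non-overlapping ellipsoidal cells on the grid, each
#' containing an interior ellipsoidal nucleus, and rasterizes them into
#' paired nucleus/cell label volumes. Cells are laid out on a jittered
#' lattice so that non-overlap is guaranteed by construction; if the grid
#' cannot host the requested number of cells an error reports how many would
#' fit. Cell semi-axes are drawn uniformly from \code{radiusXY} (x and y,
#' in voxels) and \code{radiusZ}; the nucleus shares the cell center up to a
#' small jitter and has semi-axes \code{nucleusScale} times the cell's.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param nCells number of cells to place (0 gives all-zero volumes).
#' @param seed RNG seed.
#' @param radiusXY range (voxels) for the x/y cell semi-axes.
#' @param radiusZ range (voxels) for the z cell semi-axis.
#' @param nucleusScale range for the nucleus/cell semi-axis ratio.
#' @return A \linkS4class{SegmentationSet} with labels 1..nCells
#'   (0 = background).
#' @examples
#' seg <- makeCellGeometry(VoxelGrid(c(64, 64, 16)), nCells = 2, seed = 1)
#' cellVolumes(seg)
#' @export
makeCellGeometry <- function(grid, nCells, seed = 1L,
                             radiusXY = c(8, 12), radiusZ = c(3, 5),
                             nucleusScale = c(0.40, 0.55)) {
    stopifnot(is(grid, "VoxelGrid"), nCells >= 0)
    sh <- voxelShape(grid)
    nuc <- array(0L, dim = sh)
    cel <- array(0L, dim = sh)
    if (nCells == 0L)
        return(SegmentationSet(grid, nuc, cel))

    rmax <- max(radiusXY)
    slot <- 2L * ceiling(rmax) + 2L    # lattice pitch guaranteeing no overlap
    nslx <- sh[1L] %/% slot
    nsly <- sh[2L] %/% slot
    capacity <- nslx * nsly
    if (sh[3L] < 2 * max(radiusZ) + 3)
        stop("grid too shallow in z for cells of semi-axis ",
             max(radiusZ), " voxels")
    if (nCells > capacity)
        stop("cannot place ", nCells, " cells on this grid; only ",
             capacity, " non-overlapping cells fit")

    set.seed(seed)
    slots <- sample.int(capacity, nCells)
    for (k in seq_len(nCells)) {
        sx <- (slots[k] - 1L) %% nslx
        sy <- (slots[k] - 1L) %/% nslx
        rx <- runif(1, radiusXY[1L], radiusXY[2L])
        ry <- runif(1, radiusXY[1L], radiusXY[2L])
        rz <- runif(1, radiusZ[1L], radiusZ[2L])
        # jitter keeps the ellipsoid strictly inside its lattice slot
        jx <- runif(1, -(slot / 2 - rx - 1), slot / 2 - rx - 1)
        jy <- runif(1, -(slot / 2 - ry - 1), slot / 2 - ry - 1)
        cx <- sx * slot + slot / 2 + jx
        cy <- sy * slot + slot / 2 + jy
        cz <- sh[3L] / 2 + runif(1, -0.5, 0.5)

        ns <- runif(1, nucleusScale[1L], nucleusScale[2L])
        nrx <- ns * rx; nry <- ns * ry; nrz <- ns * rz
        ox <- runif(1, -0.15, 0.15) * rx
        oy <- runif(1, -0.15, 0.15) * ry

        xs <- max(1L, floor(cx - rx)):min(sh[1L], ceiling(cx + rx))
        ys <- max(1L, floor(cy - ry)):min(sh[2L], ceiling(cy + ry))
        zs <- max(1L, floor(cz - rz)):min(sh[3L], ceiling(cz + rz))
        gx <- rep(xs, times = length(ys) * length(zs))
        gy <- rep(rep(ys, each = length(xs)), times = length(zs))
        gz <- rep(zs, each = length(xs) * length(ys))
        incell <- ((gx - cx) / rx)^2 + ((gy - cy) / ry)^2 +
            ((gz - cz) / rz)^2 <= 1
        innuc <- ((gx - cx - ox) / nrx)^2 + ((gy - cy - oy) / nry)^2 +
            ((gz - cz) / nrz)^2 <= 1
        innuc <- innuc & incell   # nucleus voxels are a subset by construction
        idx <- cbind(gx, gy, gz)
        cel[idx[incell, , drop = FALSE]] <- k
        nuc[idx[innuc, , drop = FALSE]] <- k
        if (!any(innuc))
            stop("degenerate geometry: cell ", k, " received no nucleus voxel")
    }
    SegmentationSet(grid, nuc, cel)
}
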