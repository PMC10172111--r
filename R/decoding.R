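#' The standard two-base color mapping
#'
#' Four-color dinucleotide encoding: identical-base pairs map to color 0,
#' \{AC, CA, GT, TG\} to 1, \{AG, GA, CT, TC\} to 2 and \{AT, TA, CG, GC\} to
#' 3. Under this scheme any single-base change alters at least two colors in
#' the overlapping read-out, which is what gives two-base encoding its
#' error-rejection property.
#'
#' @return named integer vector of length 16 (dinucleotide -> color 0..3).
#' @examples
#' twoBaseColorMap()[["AT"]]   # 3
#' @export
twoBaseColorMap <- function() {
    b <- c("A", "C", "G", "T")
    m <- matrix(c(0, 1, 2, 3,
                  1, 0, 3, 2,
                  2, 3, 0, 1,
                  3, 2, 1, 0), 4, 4, byrow = TRUE,
                dimnames = list(b, b))
    v <- as.integer(t(m))
    names(v) <- as.vector(t(outer(b, b, paste0)))
    v
}

#' Encode a DNA barcode into color space
#'
#' Prepends/appends the anchor bases and reads the colors of all consecutive
#' overlapping dinucleotides, so a 5-nt barcode with one anchor on each side
#' yields a 6-round color sequence.
#'
#' @param barcode DNA barcode over \{A,C,G,T\}.
#' @param map named dinucleotide -> color map (default
#'   \code{\link{twoBaseColorMap}}).
#' @param anchors character(2), the 5' and 3' anchor bases.
#' @return integer vector of colors (0..3), length nchar(barcode) + 1.
#' @examples
#' encodeBarcode("ACGTC")   # 0 1 3 1 2 1
#' @export
encodeBarcode <- function(barcode, map = twoBaseColorMap(),
                          anchors = c("A", "A")) {
    if (!grepl("^[ACGT]+$", barcode))
        stop("barcode must be over {A,C,G,T}: ", barcode)
    s <- strsplit(paste0(anchors[1L], barcode, anchors[2L]), "")[[1L]]
    dinucs <- paste0(s[-length(s)], s[-1L])
    unname(map[dinucs])
}

#' Build a codebook from gene/barcode pairs
#'
#' Encodes every barcode into color space and verifies that no two genes
#' share a color sequence (a collision is a construction error).
#'
#' @param genes gene names.
#' @param barcodes DNA barcodes, one per gene, equal lengths.
#' @param map dinucleotide color map.
#' @param anchors character(2) anchor bases.
#' @return A \linkS4class{Codebook}.
#' @export
buildCodebook <- function(genes, barcodes, map = twoBaseColorMap(),
                          anchors = c("A", "A")) {
    if (length(genes) == 0L) stop("empty codebook")
    if (length(unique(nchar(barcodes))) != 1L)
        stop("all barcodes must have the same length")
    colors <- t(vapply(barcodes, encodeBarcode, map = map, anchors = anchors,
                       FUN.VALUE = integer(nchar(barcodes[1L]) + 1L)))
    rownames(colors) <- genes
    new("Codebook", genes = genes, barcodes = barcodes, colors = colors,
        colorMap = map, anchors = anchors)
}

#' Generate a random collision-free codebook
#'
#' Samples random barcodes of the given length and keeps only those whose
#' color sequences are unique, retrying until every gene has a distinct
#' codeword.
#'
#' @param genes gene names to encode.
#' @param barcodeLength barcode length in nt (default 5, i.e. 6 color
#'   rounds with the default anchors).
#' @param seed RNG seed.
#' @inheritParams buildCodebook
#' @return A \linkS4class{Codebook}.
#' @export
makeCodebook <- function(genes, barcodeLength = 5L, seed = 1L,
                         map = twoBaseColorMap(), anchors = c("A", "A")) {
    set.seed(seed)
    n <- length(genes)
    if (n > 4^barcodeLength / 2)
        stop("too many genes for barcode length ", barcodeLength)
    bases <- c("A", "C", "G", "T")
    picked <- character(0)
    keys <- character(0)
    while (length(picked) < n) {
        cand <- paste(sample(bases, barcodeLength, replace = TRUE),
                      collapse = "")
        key <- paste(encodeBarcode(cand, map, anchors), collapse = "")
        if (!key %in% keys) {
            picked <- c(picked, cand)
            keys <- c(keys, key)
        }
    }
    buildCodebook(genes, picked, map = map, anchors = anchors)
}

#' Simulate per-round 4-channel intensities for decoded reads
#'
#' For each read, emits one intensity row per color round: the gene's
#' expected color channel gets value 1, the other three get 0, and Gaussian
#' noise of sd \code{noiseSd} (truncated at 0) is added to all four. The true
#' gene is carried along in \code{true_gene} for validation.
#'
#' @param reads a read table with a \code{gene} column, or a character
#'   vector of genes (one per dot).
#' @param codebook a \linkS4class{Codebook} covering every gene.
#' @param noiseSd nonnegative noise standard deviation.
#' @param seed RNG seed.
#' @return data.frame: dot_id, round, ch1..ch4, true_gene.
#' @export
simulateIntensities <- function(reads, codebook, noiseSd = 0, seed = 1L) {
    genes <- if (is.character(reads)) reads else reads$gene
    if (noiseSd < 0) stop("'noiseSd' must be nonnegative")
    miss <- setdiff(unique(genes), cbGenes(codebook))
    if (length(miss))
        stop("gene(s) missing from codebook: ", paste(miss, collapse = ", "))
    set.seed(seed)
    R <- nRounds(codebook)
    n <- length(genes)
    gi <- match(genes, cbGenes(codebook))
    col <- cbColors(codebook)[gi, , drop = FALSE]     # n x R colors
    dot <- rep(seq_len(n), each = R)
    rnd <- rep(seq_len(R), times = n)
    colorOf <- as.vector(t(col))                      # per (dot, round)
    base <- matrix(0, n * R, 4L)
    base[cbind(seq_len(n * R), colorOf + 1L)] <- 1
    if (noiseSd > 0)
        base <- pmax(base + matrix(rnorm(length(base), sd = noiseSd),
                                   nrow(base)), 0)
    data.frame(dot_id = dot, round = rnd, ch1 = base[, 1L], ch2 = base[, 2L],
               ch3 = base[, 3L], ch4 = base[, 4L],
               true_gene = genes[dot], stringsAsFactors = FALSE)
}

#' Call the dominant color of every dot and round
#'
#' L2-normalizes each dot/round 4-vector and takes the unique argmax channel.
#' A round with tied maxima or an all-zero vector makes the whole dot
#' uncallable (rejection, not an error).
#'
#' @param dots data.frame with dot_id, round, ch1..ch4.
#' @return data.frame per dot x round: dot_id, round, color (0..3 or NA),
#'   domval (L2-normalized dominant value), ok.
#' @export
callColors <- function(dots) {
    ch <- as.matrix(dots[, c("ch1", "ch2", "ch3", "ch4")])
    if (any(!is.finite(ch)) || any(ch < 0))
        stop("intensities must be finite and nonnegative")
    nrm <- sqrt(rowSums(ch^2))
    mx <- pmax(ch[, 1L], ch[, 2L], ch[, 3L], ch[, 4L])
    ties <- rowSums(ch == mx) > 1L
    zero <- nrm == 0
    ok <- !ties & !zero
    color <- max.col(ch, ties.method = "first") - 1L
    color[!ok] <- NA_integer_
    domval <- ifelse(ok, mx / nrm, NA_real_)
    data.frame(dot_id = dots$dot_id, round = dots$round, color = color,
               domval = domval, ok = ok)
}

#' Decoding quality score
#'
#' Q = mean over rounds of -log(L2-normalized dominant channel value); 0 when
#' every round is a pure single-channel signal, larger when intensity leaks
#' into other channels. Lower is better.
#'
#' @param v dominant values in (0, 1], one per round.
#' @param logBase base of the logarithm (default natural log).
#' @return nonnegative scalar.
#' @examples
#' qualityScore(c(0.9, 0.8))   # 0.16425...
#' @export
qualityScore <- function(v, logBase = exp(1)) {
    if (any(v <= 0)) stop("dominant values must be positive")
    mean(-log(v, base = logBase))
}

#' Match called color sequences against a codebook
#'
#' A dot is assigned gene g iff its color sequence equals g's codeword
#' exactly and its quality score is at most \code{qMax}; otherwise it is
#' rejected with a reason (\code{no_match} or \code{low_quality}). No error
#' correction is attempted: mismatches are rejected, not rescued.
#'
#' @param calls output of \code{\link{callColors}}.
#' @param codebook a \linkS4class{Codebook}.
#' @param qMax quality threshold (> 0); default 0.5.
#' @param logBase log base for the quality score.
#' @return data.frame per dot: dot_id, gene (NA if rejected), quality,
#'   reason (assigned | bad_call | no_match | low_quality).
#' @export
matchAndFilter <- function(calls, codebook, qMax = 0.5, logBase = exp(1)) {
    if (qMax <= 0) stop("'qMax' must be positive")
    if (length(cbGenes(codebook)) == 0L) stop("empty codebook")
    o <- order(calls$dot_id, calls$round)
    calls <- calls[o, ]
    R <- nRounds(codebook)
    ids <- unique(calls$dot_id)
    okByDot <- tapply(calls$ok, calls$dot_id, all)[as.character(ids)]
    key <- tapply(calls$color, calls$dot_id,
                  paste, collapse = "")[as.character(ids)]
    qual <- tapply(calls$domval, calls$dot_id, function(v)
        if (anyNA(v)) NA_real_ else qualityScore(v, logBase))[as.character(ids)]
    codeKey <- apply(cbColors(codebook), 1L, paste, collapse = "")
    gi <- match(key, codeKey)
    gene <- cbGenes(codebook)[gi]
    reason <- rep("assigned", length(ids))
    reason[!okByDot] <- "bad_call"
    reason[okByDot & is.na(gi)] <- "no_match"
    reason[okByDot & !is.na(gi) & qual > qMax] <- "low_quality"
    gene[reason != "assigned"] <- NA_character_
    data.frame(dot_id = ids, gene = gene, quality = as.numeric(qual),
               reason = reason, stringsAsFactors = FALSE)
}

#' Decode dots end to end
#'
#' Runs \code{\link{callColors}} then \code{\link{matchAndFilter}}.
#'
#' @inheritParams callColors
#' @inheritParams matchAndFilter
#' @return per-dot decode table (see \code{\link{matchAndFilter}}).
#' @export
decodeDots <- function(dots, codebook, qMax = 0.5, logBase = exp(1)) {
    matchAndFilter(callColors(dots), codebook, qMax = qMax,
                   logBase = logBase)
}
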