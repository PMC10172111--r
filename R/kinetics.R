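#' @importFrom stats lm coef nls predict var sd cor wilcox.test hclust as.dist
NULL

#' Normalize counts across timepoints against reference genes
#'
#' Reference (control) genes are probed for total rather than labeled RNA
#' and are assumed time-invariant, so differences in their mean reads per
#' cell across chase timepoints measure technical batch variation. Each
#' timepoint t is rescaled by s_t = (grand mean of per-timepoint reference
#' means) / (mean reference reads per cell at t), applied to all four
#' assays, after which the per-timepoint reference means are equal. The
#' transform is idempotent.
#'
#' @param cm a \linkS4class{CompartmentMatrix}.
#' @param referenceGenes reference gene names present in \code{rownames(cm)}.
#' @return the rescaled \linkS4class{CompartmentMatrix}; the scales used are
#'   stored in \code{metadata(cm)$normalization_scales}.
#' @export
normalizeCounts <- function(cm, referenceGenes) {
    refs <- intersect(referenceGenes, rownames(cm))
    if (length(refs) == 0L)
        stop("none of the reference genes are present in the matrix")
    tp <- colData(cm)$timepoint_h
    tps <- sort(unique(tp))
    refMean <- vapply(tps, function(t) {
        sel <- tp == t
        sum(assay(cm, "total")[refs, sel, drop = FALSE]) / sum(sel)
    }, numeric(1L))
    if (any(refMean == 0))
        stop("zero reference-gene signal at timepoint(s) ",
             paste(tps[refMean == 0], collapse = ", "))
    grand <- mean(refMean)
    scales <- grand / refMean
    sc <- scales[match(tp, tps)]
    for (a in c("nucleus", "middle", "periphery", "total")) {
        m <- assay(cm, a)
        SummarizedExperiment::assay(cm, a, withDimnames = FALSE) <-
            m %*% Matrix::Diagonal(x = sc)
    }
    metadata(cm)$normalization_scales <- setNames(scales, tps)
    validObject(cm)
    cm
}

#' Convert counts to concentrations (copies per voxel)
#'
#' Divides each cell's (normalized) counts by the cell's total volume in
#' voxels, removing the coupling between cell size and read count so that
#' kinetic fits operate on concentrations.
#'
#' @param cm a \linkS4class{CompartmentMatrix} whose colData carries
#'   \code{volume_voxels}.
#' @param assayName which assay to convert (default "total").
#' @return a gene x cell sparse matrix of concentrations.
#' @export
toConcentration <- function(cm, assayName = "total") {
    v <- colData(cm)$volume_voxels
    if (any(v <= 0)) stop("zero or negative cell volume")
    assay(cm, assayName) %*% Matrix::Diagonal(x = 1 / v)
}

#' Fit the degradation constant beta
#'
#' Under first-order decay with no synthesis after the pulse, ln X(t) is
#' linear in chase time with slope -beta. Fits ordinary least squares of
#' ln X on t (zeros and non-finite values dropped); at least 3 positive
#' timepoints are required. The alternative \code{mode = "nls"} fits
#' X = A exp(-beta t) by nonlinear least squares, reporting R-squared on the
#' concentration scale.
#'
#' @param t chase times (h).
#' @param x mean concentration per timepoint (copies/voxel).
#' @param mode "loglinear" (default) or "nls".
#' @return list: beta (1/h), r2, x0 (fitted value at t = 0), n_used, ok.
#' @examples
#' fitBeta(c(0, 2, 4, 6), 2 * exp(-0.5 * c(0, 2, 4, 6)))$beta   # 0.5
#' @export
fitBeta <- function(t, x, mode = c("loglinear", "nls")) {
    mode <- match.arg(mode)
    use <- is.finite(x) & x > 0 & is.finite(t)
    if (sum(use) < 3L)
        return(list(beta = NA_real_, r2 = NA_real_, x0 = NA_real_,
                    n_used = sum(use), ok = FALSE))
    t <- t[use]; x <- x[use]
    if (mode == "loglinear") {
        fit <- lm(log(x) ~ t)
        beta <- -unname(coef(fit)[2L])
        r2 <- suppressWarnings(summary(fit)$r.squared)
        if (var(log(x)) == 0) r2 <- NA_real_   # flat series: slope 0, no fit
        x0 <- exp(unname(coef(fit)[1L]))
    } else {
        start <- list(A = max(x), b = 0.3)
        fit <- try(minpack.lm::nlsLM(x ~ A * exp(-b * t), start = start),
                   silent = TRUE)
        if (inherits(fit, "try-error"))
            return(list(beta = NA_real_, r2 = NA_real_, x0 = NA_real_,
                        n_used = length(t), ok = FALSE))
        beta <- unname(coef(fit)["b"])
        ss_res <- sum((x - predict(fit))^2)
        ss_tot <- sum((x - mean(x))^2)
        r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
        x0 <- unname(coef(fit)["A"])
    }
    list(beta = beta, r2 = r2, x0 = x0, n_used = length(t), ok = TRUE)
}

#' Estimate the synthesis constant alpha from the pulse solution
#'
#' With zero-order synthesis during a pulse of length tau and first-order
#' decay, starting from X(0) = 0, the concentration at the end of the pulse
#' is X0 = (alpha/beta)(1 - exp(-beta tau)); inverting gives alpha =
#' beta X0 / (1 - exp(-beta tau)). As beta -> 0 this tends to the
#' zero-degradation limit X0/tau, which is also the fallback when beta <= 0
#' (flagged via the \code{"mode"} attribute).
#'
#' @param x0 concentration at chase 0 (copies/voxel).
#' @param beta degradation constant (1/h).
#' @param pulseHours pulse duration tau (h).
#' @return alpha (copies/voxel/h) with attribute \code{mode} =
#'   "closed_form" or "linear_fallback".
#' @examples
#' estimateAlpha(2, 0.5, 1)   # 2.5415...
#' @export
estimateAlpha <- function(x0, beta, pulseHours = 1) {
    tau <- pulseHours
    if (!is.finite(beta) || beta <= 0 || beta * tau < 1e-12) {
        a <- x0 / tau
        attr(a, "mode") <- "linear_fallback"
        return(a)
    }
    a <- beta * x0 / (1 - exp(-beta * tau))
    attr(a, "mode") <- "closed_form"
    a
}

#' Fit the nuclear export constant lambda
#'
#' Regresses the nuclear read fraction y(t) = nuclear / (nuclear +
#' cytoplasmic) on chase time; lambda is minus the slope, and the intercept
#' is the initial nuclear fraction f0. lambda describes the decline of the
#' nucleocytoplasmic distribution rather than a pure export rate, since
#' nuclear and cytoplasmic degradation are not separated.
#'
#' @param t chase times (h).
#' @param y nuclear fraction per timepoint, in [0, 1].
#' @return list: lam (1/h), f0, r2, n_used, ok.
#' @examples
#' fitLambda(c(0, 2, 4, 6), c(0.8, 0.6, 0.4, 0.2))$lam   # 0.1
#' @export
fitLambda <- function(t, y) {
    use <- is.finite(y) & is.finite(t)
    if (sum(use) < 3L)
        return(list(lam = NA_real_, f0 = NA_real_, r2 = NA_real_,
                    n_used = sum(use), ok = FALSE))
    fit <- lm(y[use] ~ t[use])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (var(y[use]) == 0) r2 <- NA_real_
    list(lam = -unname(coef(fit)[2L]), f0 = unname(coef(fit)[1L]),
         r2 = r2, n_used = sum(use), ok = TRUE)
}

#' Fit the cytoplasmic translocation constant gamma
#'
#' Regresses the mean DR of all cytoplasmic reads (pooled across cells) on
#' chase time; gamma is the slope with its sign retained — positive gamma is
#' outward drift toward the membrane, negative gamma inward relocation.
#'
#' @param t chase times (h).
#' @param drMean mean DR per timepoint.
#' @return list: gamma (DR/h), r2, n_used, ok.
#' @examples
#' fitGamma(c(0, 2, 4, 6), c(0.30, 0.34, 0.38, 0.42))$gamma   # 0.02
#' @export
fitGamma <- function(t, drMean) {
    use <- is.finite(drMean) & is.finite(t)
    if (sum(use) < 3L)
        return(list(gamma = NA_real_, r2 = NA_real_, n_used = sum(use),
                    ok = FALSE))
    fit <- lm(drMean[use] ~ t[use])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (var(drMean[use]) == 0) r2 <- NA_real_
    list(gamma = unname(coef(fit)[2L]), r2 = r2, n_used = sum(use),
         ok = TRUE)
}

# Per-gene timecourse summaries over the usable (non-excluded) chase times.
# Returns list(t, X [gene x tp mean concentration], y [nuclear fraction],
# drm [mean DR of cytoplasmic reads], nCells per tp).
.geneTimecourses <- function(cm, design, reads = NULL,
                             yMode = c("ratio_of_means", "mean_of_ratios")) {
    yMode <- match.arg(yMode)
    tuse <- setdiff(design@chaseHours, design@excludedChaseHours)
    tp <- colData(cm)$timepoint_h
    conc <- toConcentration(cm)
    genes <- rownames(cm)
    X <- matrix(NA_real_, length(genes), length(tuse),
                dimnames = list(genes, tuse))
    Y <- X
    nCells <- integer(length(tuse))
    for (j in seq_along(tuse)) {
        sel <- tp == tuse[j]
        nCells[j] <- sum(sel)
        if (!any(sel)) next
        X[, j] <- Matrix::rowMeans(conc[, sel, drop = FALSE])
        nucS <- Matrix::rowSums(assay(cm, "nucleus")[, sel, drop = FALSE])
        cytS <- Matrix::rowSums(assay(cm, "middle")[, sel, drop = FALSE]) +
            Matrix::rowSums(assay(cm, "periphery")[, sel, drop = FALSE])
        if (yMode == "ratio_of_means") {
            Y[, j] <- ifelse(nucS + cytS > 0, nucS / (nucS + cytS), NA_real_)
        } else {
            nucM <- assay(cm, "nucleus")[, sel, drop = FALSE]
            totM <- nucM + assay(cm, "middle")[, sel, drop = FALSE] +
                assay(cm, "periphery")[, sel, drop = FALSE]
            frac <- as.matrix(nucM) / as.matrix(totM)
            Y[, j] <- rowMeans(frac, na.rm = TRUE)
        }
    }
    drm <- NULL
    if (!is.null(reads)) {
        cy <- reads$compartment %in% c("middle", "periphery") &
            is.finite(reads$dr) & reads$timepoint_h %in% tuse
        drm <- matrix(NA_real_, length(genes), length(tuse),
                      dimnames = list(genes, tuse))
        if (any(cy)) {
            agg <- tapply(reads$dr[cy],
                          list(factor(reads$gene[cy], levels = genes),
                               factor(reads$timepoint_h[cy], levels = tuse)),
                          mean)
            drm[, ] <- agg
        }
    }
    list(t = tuse, X = X, y = Y, drm = drm, nCells = nCells)
}

#' Estimate all four kinetic constants per gene
#'
#' Builds per-gene timecourses from the non-excluded chase timepoints of a
#' normalized \linkS4class{CompartmentMatrix} and fits synthesis (alpha),
#' degradation (beta), nuclear export (lambda) and — when a read table with
#' DR values is supplied — cytoplasmic translocation (gamma). X0 for the
#' alpha inversion is the observed mean concentration at chase 0 (or the
#' fitted value when 0 h is excluded). QC follows the positive-value and
#' goodness-of-fit rule: \code{qc_pass = alpha > 0 & beta > 0 & r2_beta >=
#' r2Min}; estimates failing QC are still emitted with flags so that
#' filtering remains the caller's choice. With \code{byPhase = TRUE} the fits
#' are repeated within each cell-cycle phase (colData \code{phase}), giving
#' up to 12 parameters per gene over three phases.
#'
#' @param cm a (normalized) \linkS4class{CompartmentMatrix}.
#' @param design a \linkS4class{PulseChaseDesign}.
#' @param reads optional annotated read table (for gamma).
#' @param byPhase estimate per cell-cycle phase instead of pooled.
#' @param r2Min R-squared threshold on the beta fit (default 0.5).
#' @param betaMode "loglinear" or "nls".
#' @param yMode nuclear fraction as ratio-of-means (default) or
#'   mean-of-ratios.
#' @return data.frame: gene, phase, alpha, beta, lam, f0, gamma, r2_beta,
#'   r2_lambda, r2_gamma, qc_pass, n_cells_used, alpha_mode.
#' @export
estimateAll <- function(cm, design, reads = NULL, byPhase = FALSE,
                        r2Min = 0.5, betaMode = c("loglinear", "nls"),
                        yMode = c("ratio_of_means", "mean_of_ratios")) {
    betaMode <- match.arg(betaMode)
    yMode <- match.arg(yMode)
    if (byPhase) {
        ph <- colData(cm)$phase
        if (is.null(ph) || anyNA(ph))
            stop("byPhase = TRUE requires a complete colData 'phase' column")
        out <- lapply(sort(unique(ph)), function(p) {
            sub <- cm[, ph == p]
            rsub <- NULL
            if (!is.null(reads)) {
                keys <- paste(colData(sub)$cell_id, colData(sub)$timepoint_h)
                rsub <- reads[paste(reads$cell_id, reads$timepoint_h) %in%
                              keys, , drop = FALSE]
            }
            est <- estimateAll(sub, design, reads = rsub, byPhase = FALSE,
                               r2Min = r2Min, betaMode = betaMode,
                               yMode = yMode)
            est$phase <- p
            est
        })
        return(do.call(rbind, out))
    }
    tc <- .geneTimecourses(cm, design, reads = reads, yMode = yMode)
    genes <- rownames(cm)
    n <- length(genes)
    res <- data.frame(gene = genes, phase = "all", alpha = NA_real_,
                      beta = NA_real_, lam = NA_real_, f0 = NA_real_,
                      gamma = NA_real_, r2_beta = NA_real_,
                      r2_lambda = NA_real_, r2_gamma = NA_real_,
                      qc_pass = FALSE, n_cells_used = sum(tc$nCells),
                      alpha_mode = NA_character_, stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
        fb <- fitBeta(tc$t, tc$X[i, ], mode = betaMode)
        res$beta[i] <- fb$beta
        res$r2_beta[i] <- fb$r2
        if (fb$ok) {
            x0 <- if (0 %in% tc$t) tc$X[i, match(0, tc$t)] else fb$x0
            a <- estimateAlpha(x0, fb$beta, design@pulseHours)
            res$alpha[i] <- as.numeric(a)
            res$alpha_mode[i] <- attr(a, "mode")
        }
        fl <- fitLambda(tc$t, tc$y[i, ])
        res$lam[i] <- fl$lam
        res$f0[i] <- fl$f0
        res$r2_lambda[i] <- fl$r2
        if (!is.null(tc$drm)) {
            fg <- fitGamma(tc$t, tc$drm[i, ])
            res$gamma[i] <- fg$gamma
            res$r2_gamma[i] <- fg$r2
        }
    }
    res$qc_pass <- !is.na(res$alpha) & !is.na(res$beta) &
        !is.na(res$r2_beta) & res$alpha > 0 & res$beta > 0 &
        res$r2_beta >= r2Min
    res
}
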