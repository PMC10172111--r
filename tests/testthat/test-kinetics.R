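test_that("beta fit is exact on noiseless exponentials", {
    t <- c(0, 2, 4, 6)
    fb <- fitBeta(t, 2 * exp(-0.5 * t))
    expect_equal(fb$beta, 0.5, tolerance = 1e-9)
    expect_equal(fb$r2, 1.0, tolerance = 1e-9)
    expect_equal(fb$x0, 2, tolerance = 1e-9)
})

test_that("beta fit equals the hand OLS slope on irregular series", {
    t <- c(0, 2, 4, 6)
    x <- c(1.0, 0.9, 0.5, 0.2)
    # independent closed-form OLS on (t, ln x)
    lx <- log(x)
    slope <- sum((t - mean(t)) * (lx - mean(lx))) / sum((t - mean(t))^2)
    fb <- fitBeta(t, x)
    expect_equal(fb$beta, -slope, tolerance = 1e-12)
    r2 <- 1 - sum((lx - (mean(lx) + slope * (t - mean(t))))^2) /
        sum((lx - mean(lx))^2)
    expect_equal(fb$r2, r2, tolerance = 1e-12)
    # nonlinear mode agrees on noiseless exponentials
    fn <- fitBeta(t, 2 * exp(-0.5 * t), mode = "nls")
    expect_equal(fn$beta, 0.5, tolerance = 1e-6)
})

test_that("flat or short series flag the beta fit as unusable", {
    t <- c(0, 2, 4, 6)
    fb <- fitBeta(t, rep(3, 4))
    expect_equal(fb$beta, 0, tolerance = 1e-12)
    expect_true(is.na(fb$r2))
    expect_false(fitBeta(t, c(1, 0, 0, 0))$ok)   # < 3 positive points
})

test_that("alpha inversion matches the closed form and its small-beta limit", {
    a <- estimateAlpha(2, 0.5, 1)
    expect_equal(as.numeric(a), 0.5 * 2 / (1 - exp(-0.5)), tolerance = 1e-12)
    expect_equal(round(as.numeric(a), 4), 2.5415)
    expect_identical(attr(a, "mode"), "closed_form")
    # beta -> 0 converges to X0 / tau
    expect_equal(as.numeric(estimateAlpha(2, 1e-9, 1)), 2, tolerance = 1e-6)
    a0 <- estimateAlpha(2, 0, 1)
    expect_equal(as.numeric(a0), 2)
    expect_identical(attr(a0, "mode"), "linear_fallback")
    expect_equal(as.numeric(estimateAlpha(0, 0.5, 1)), 0)
})

test_that("lambda fit is exact on lines and matches the hand OLS oracle", {
    t <- c(0, 2, 4, 6)
    fl <- fitLambda(t, c(0.8, 0.6, 0.4, 0.2))
    expect_equal(fl$lam, 0.1, tolerance = 1e-9)
    expect_equal(fl$f0, 0.8, tolerance = 1e-9)
    expect_equal(fitLambda(t, rep(0.5, 4))$lam, 0, tolerance = 1e-12)
    # hand OLS: sum((t-3)(y-ybar)) / sum((t-3)^2) = -2.04 / 20
    fl2 <- fitLambda(t, c(0.9, 0.7, 0.52, 0.28))
    expect_equal(fl2$lam, 2.04 / 20, tolerance = 1e-12)
    expect_equal(fl2$lam, 0.102, tolerance = 1e-9)
})

test_that("gamma fit keeps the drift sign", {
    t <- c(0, 2, 4, 6)
    expect_equal(fitGamma(t, c(0.30, 0.34, 0.38, 0.42))$gamma, 0.02,
                 tolerance = 1e-9)
    expect_equal(fitGamma(t, c(0.50, 0.44, 0.38, 0.32))$gamma, -0.03,
                 tolerance = 1e-9)
    expect_equal(fitGamma(t, rep(0.4, 4))$gamma, 0, tolerance = 1e-12)
    expect_false(fitGamma(t, c(0.3, NA, NA, 0.4))$ok)
})

test_that("reference normalization reproduces the worked scales", {
    # reference means 10 and 5 across two timepoints: grand mean 7.5,
    # scales 0.75 and 1.5; a count of 4 at the second timepoint becomes 6
    nuc <- rbind(REF = c(10, 5), GEN = c(8, 4))
    cm <- toyCM(nuc, nuc * 0, nuc * 0, timepoint_h = c(0, 2),
                volume_voxels = c(100, 100))
    cmn <- normalizeCounts(cm, "REF")
    expect_equal(unname(metadata(cmn)$normalization_scales), c(0.75, 1.5))
    expect_equal(as.numeric(assay(cmn, "total")["GEN", ]), c(6, 6))
    expect_equal(as.numeric(assay(cmn, "total")["REF", ]), c(7.5, 7.5))
})

test_that("normalization equalizes reference means and is idempotent", {
    set.seed(40)
    nuc <- matrix(rpois(60, 8), 6, 10,
                  dimnames = list(c(sprintf("G%d", 1:4), "REF1", "REF2"),
                                  NULL))
    mid <- matrix(rpois(60, 5), 6, 10)
    cm <- toyCM(nuc, mid, mid * 0, timepoint_h = rep(c(0, 2, 4, 6, 6), 2),
                volume_voxels = rep(1000, 10))
    refs <- c("REF1", "REF2")
    cmn <- normalizeCounts(cm, refs)
    tp <- colData(cmn)$timepoint_h
    means <- vapply(sort(unique(tp)), function(t)
        sum(assay(cmn, "total")[refs, tp == t]) / sum(tp == t), numeric(1))
    expect_lt(max(means) - min(means), 1e-9)
    cmn2 <- normalizeCounts(cmn, refs)
    expect_equal(as.matrix(assay(cmn2, "total")),
                 as.matrix(assay(cmn, "total")), tolerance = 1e-9)
    # identity when reference means are already equal
    expect_equal(unname(metadata(cmn2)$normalization_scales),
                 rep(1, 4), tolerance = 1e-9)
})

test_that("concentration conversion divides by total cell voxels", {
    nuc <- rbind(G = c(50, 0))
    cm <- toyCM(nuc, nuc * 0, nuc * 0, timepoint_h = c(0, 2),
                volume_voxels = c(10000, 10000))
    conc <- toConcentration(cm)
    expect_equal(as.numeric(conc["G", ]), c(0.005, 0))
    cm2 <- toyCM(nuc, nuc * 0, nuc * 0, timepoint_h = c(0, 2),
                 volume_voxels = c(20000, 20000))
    expect_equal(as.numeric(toConcentration(cm2)["G", ]), c(0.0025, 0))
})

test_that("estimateAll applies the positive-value and R-squared QC gate", {
    t <- c(0, 2, 4, 6)
    # residual pattern (1,-1,-1,1) is orthogonal to (1, t): the OLS slope is
    # untouched and R^2 = SSreg / (SSreg + SSres) is exact by construction
    mkSeries <- function(r2) {
        b <- 0.5; ssreg <- b^2 * sum((t - mean(t))^2)
        s <- sqrt(ssreg * (1 - r2) / r2 / 4)
        exp(1 - b * t + c(1, -1, -1, 1) * s)
    }
    X <- rbind(PASS = mkSeries(0.51), FAIL = mkSeries(0.49))
    cm <- seriesCM(X, t)
    des <- PulseChaseDesign(chaseHours = t, excludedChaseHours = numeric(0))
    est <- estimateAll(cm, des)
    expect_equal(est$r2_beta[est$gene == "PASS"], 0.51, tolerance = 1e-9)
    expect_equal(est$r2_beta[est$gene == "FAIL"], 0.49, tolerance = 1e-9)
    expect_true(est$qc_pass[est$gene == "PASS"])
    expect_false(est$qc_pass[est$gene == "FAIL"])
})

test_that("phase-resolved estimation is per-phase bookkeeping over one fit", {
    t <- rep(c(0, 2, 4, 6), 2)
    X <- matrix(rep(2 * exp(-0.5 * c(0, 2, 4, 6)), each = 1), 1, 8,
                dimnames = list("G", NULL))
    X <- rbind(G = c(2 * exp(-0.5 * c(0, 2, 4, 6)),
                     1 * exp(-0.2 * c(0, 2, 4, 6))))
    cm <- toyCM(X, X * 0, X * 0, timepoint_h = t,
                volume_voxels = rep(1, 8),
                phase = rep(c("G1", "G2/M"), each = 4))
    des <- PulseChaseDesign(chaseHours = c(0, 2, 4, 6),
                            excludedChaseHours = numeric(0))
    est <- estimateAll(cm, des, byPhase = TRUE)
    expect_equal(nrow(est), 2)
    expect_equal(est$beta[est$phase == "G1"], 0.5, tolerance = 1e-9)
    expect_equal(est$beta[est$phase == "G2/M"], 0.2, tolerance = 1e-9)
    cm2 <- cm; colData(cm2)$phase <- NA_character_
    expect_error(estimateAll(cm2, des, byPhase = TRUE), "phase")
})

test_that("excluding the artifact timepoint shields the beta estimate", {
    seg <- smallSeg()
    gt <- geneTruthTable(8, nReference = 2, seed = 41)
    cfg <- simConfig(9, gt, detectionEfficiency = 1, seed = 42)
    sim <- simulateExperiment(cfg, seg, inflateChase = 1,
                              inflateFactor = 2.5)
    r <- annotateReads(sim$reads[, c("gene", "x", "y", "z", "timepoint_h")],
                       seg)
    cm <- buildCompartmentMatrix(r, seg, genes = gt$gene)
    cmn <- normalizeCounts(cm, gt$gene[gt$is_reference])
    desEx <- PulseChaseDesign()                      # excludes 1 h
    desIn <- PulseChaseDesign(excludedChaseHours = numeric(0))
    eEx <- estimateAll(cmn, desEx)
    eIn <- estimateAll(cmn, desIn)
    true <- gt$beta[match(eEx$gene, gt$gene)]
    kin <- !gt$is_reference[match(eEx$gene, gt$gene)]
    errEx <- mean(abs(eEx$beta[kin] - true[kin]))
    errIn <- mean(abs(eIn$beta[kin] - true[kin]))
    expect_lt(errEx, errIn)
})
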