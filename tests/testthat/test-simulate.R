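test_that("molecule tallies conserve born = alive + degraded", {
    seg <- smallSeg()
    gt <- geneTruthTable(5, nReference = 2, seed = 21)
    cfg <- simConfig(9, gt, detectionEfficiency = 0.5, seed = 22)
    sim <- simulateExperiment(cfg, seg)
    tl <- sim$truth$tallies
    expect_true(all(tl$born == tl$alive + tl$degraded))
    expect_true(all(tl$detected <= tl$alive))
})

test_that("zero decay keeps expected detected counts flat over the chase", {
    seg <- smallSeg()
    gt <- geneTruthTable(1, nReference = 0, seed = 23)
    gt$alpha <- 2; gt$beta <- 0; gt$lam <- 0.05
    cfg <- simConfig(9, gt, detectionEfficiency = 1, seed = 24)
    sim <- simulateExperiment(cfg, seg)
    det <- sim$truth$tallies$detected
    # Poisson counts around a common mean: every timepoint within 4 sd
    expect_true(all(abs(det - mean(det)) < 4 * sqrt(mean(det))))
})

test_that("detected copies at chase 0 match the pulse ODE closed form", {
    # X(tau) = (alpha/beta)(1 - exp(-beta tau)): 0.7869 copies/voxel for
    # alpha = 1, beta = 0.5, tau = 1 h; expected copies = X * V
    expect_equal(round((1 / 0.5) * (1 - exp(-0.5)), 4), 0.7869)
    seg <- smallSeg()
    V <- sum(cellVolumes(seg)$total_voxels)
    gt <- geneTruthTable(1, nReference = 0, seed = 26)
    gt$alpha <- 1; gt$beta <- 0.5
    cfg <- simConfig(9, gt, chaseHours = 0, detectionEfficiency = 1,
                     seed = 27)
    sim <- simulateExperiment(cfg, seg)
    expected <- V * (gt$alpha / gt$beta) * (1 - exp(-gt$beta * 1))
    expect_gt(sim$truth$tallies$born, 1e4)   # Monte-Carlo mass
    got <- sim$truth$tallies$detected
    expect_lt(abs(got - expected) / expected, 3 / sqrt(expected))
})

test_that("expected detected counts are non-increasing in chase time", {
    seg <- smallSeg()
    gt <- geneTruthTable(1, nReference = 0, seed = 28)
    gt$alpha <- 3; gt$beta <- 0.4
    cfg <- simConfig(9, gt, detectionEfficiency = 1, seed = 29)
    sim <- simulateExperiment(cfg, seg)
    det <- sim$truth$tallies$detected
    # allow Poisson noise: each step down by the decay factor within 4 sd
    expect_true(all(diff(det) < 4 * sqrt(det[-length(det)])))
    expect_lt(det[length(det)], det[1])
})

test_that("linear export schedule recovers lambda within Monte-Carlo error", {
    seg <- smallSeg()
    gt <- geneTruthTable(1, nReference = 0, seed = 30)
    gt$alpha <- 4; gt$beta <- 0.2; gt$lam <- 0.08; gt$f0 <- 0.85
    cfg <- simConfig(9, gt, detectionEfficiency = 1, seed = 31,
                     exportMode = "linear_fraction_schedule")
    sim <- simulateExperiment(cfg, seg)
    r <- sim$reads
    t <- sort(unique(r$timepoint_h))
    yt <- nt <- numeric(length(t))
    for (j in seq_along(t)) {
        sel <- r$timepoint_h == t[j]
        nt[j] <- sum(sel)
        yt[j] <- mean(r$compartment[sel] == "nucleus")
    }
    fit <- fitLambda(t, yt)
    # slope standard error from binomial sampling of each timepoint fraction
    ct <- (t - mean(t)) / sum((t - mean(t))^2)
    se <- sqrt(sum(ct^2 * yt * (1 - yt) / nt))
    expect_lt(abs(fit$lam - gt$lam), 3 * se)
    expect_equal(fit$f0, gt$f0, tolerance = 0.05)
})

test_that("reference genes emit time-constant counts spread over the cell", {
    seg <- smallSeg()
    gt <- geneTruthTable(1, nReference = 1, seed = 32)
    cfg <- simConfig(9, gt, detectionEfficiency = 1, seed = 33)
    sim <- simulateExperiment(cfg, seg)
    r <- sim$reads[sim$reads$gene == "REF01", ]
    det <- table(r$timepoint_h)
    expect_true(all(abs(det - mean(det)) < 4 * sqrt(mean(det))))
    # positions cover nucleus and cytoplasm roughly by volume share
    v <- cellVolumes(seg)
    nucShare <- sum(v$nucleus_voxels) / sum(v$total_voxels)
    expect_equal(mean(r$compartment == "nucleus"), nucShare,
                 tolerance = 0.05)
})

test_that("identical config and seed give byte-identical read tables", {
    seg <- smallSeg()
    gt <- geneTruthTable(3, nReference = 1, seed = 34)
    cfg <- simConfig(9, gt, detectionEfficiency = 0.3, seed = 35)
    a <- simulateExperiment(cfg, seg)
    b <- simulateExperiment(cfg, seg)
    expect_identical(a$reads, b$reads)
    expect_identical(a$truth$tallies, b$truth$tallies)
})

test_that("invalid configurations are rejected up front", {
    gt <- geneTruthTable(2, nReference = 0, seed = 36)
    expect_error(simConfig(4, gt, exportMode = "bogus"), "exportMode")
    expect_error(simConfig(4, gt, detectionEfficiency = 0), "(0, 1]",
                 fixed = TRUE)
    expect_error(simConfig(4, gt, phaseFractions = c(0.5, 0.5, 0.5)),
                 "summing to 1")
    gt$beta[1] <- -1
    expect_error(simConfig(4, gt), "alpha and beta")
    gt2 <- geneTruthTable(1, nReference = 1, seed = 37)
    gt2$beta[gt2$is_reference] <- 0.3
    expect_error(simConfig(4, gt2), "reference genes")
})

test_that("phase-structured marker inflation lands in the right cells", {
    sim <- simulatePhaseExpression(nCells = 120, seed = 38)
    g1sMean <- colMeans(sim$expr[g1sMarkers(), ])
    expect_gt(mean(g1sMean[sim$phase == "G1/S"]),
              2 * mean(g1sMean[sim$phase == "G1"]))
})
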