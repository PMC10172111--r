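# Two Gaussian blobs (sd 0.1) whose centers are 10 apart in parameter
# space, the separation spread over all four parameters so that it survives
# parameter-wise standardization.
twoBlobs <- function(seed, n = 50, sdev = 0.1, sep = 10) {
    set.seed(seed)
    shift <- rep(sep / 2, 4)   # ||shift|| = 10/2 * 2 = sep
    m <- rbind(matrix(rnorm(n * 4, 0, sdev), n, 4),
               matrix(rnorm(n * 4, 0, sdev), n, 4) +
                   matrix(rep(shift, each = n), n, 4))
    rownames(m) <- sprintf("g%03d", seq_len(2 * n))
    list(m = m, truth = rep(1:2, each = n))
}

clusterAgreement <- function(labels, truth) {
    tab <- table(labels, truth)
    sum(apply(tab, 2, max)) / length(truth)
}

test_that("z-scored columns have exact zero mean and unit sample sd", {
    set.seed(60)
    pm <- matrix(rnorm(200, 5, 3), 50, 4,
                 dimnames = list(sprintf("g%02d", 1:50),
                                 c("alpha", "beta", "lam", "gamma")))
    z <- zscoreParameters(pm)
    expect_lt(max(abs(colMeans(z))), 1e-9)
    expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
    pm[, 2] <- 7
    expect_error(zscoreParameters(pm), "zero-variance")
})

test_that("parameter correlations match the textbook formula", {
    pm <- cbind(a = c(1, 4, 2, 8, 5), b = c(2, 3, 1, 9, 4),
                c = -c(1, 4, 2, 8, 5))
    r <- pairwiseParameterCorrelation(pm)
    expect_equal(unname(diag(r)), rep(1, 3))
    expect_equal(r["a", "c"], -1)
    hand <- sum((pm[, 1] - mean(pm[, 1])) * (pm[, 2] - mean(pm[, 2]))) /
        sqrt(sum((pm[, 1] - mean(pm[, 1]))^2) *
             sum((pm[, 2] - mean(pm[, 2]))^2))
    expect_equal(r["a", "b"], hand, tolerance = 1e-12)
    expect_equal(r, t(r))
})

test_that("parameterMatrix pivots estimates and enforces QC per phase", {
    est <- data.frame(gene = rep(c("A", "B"), each = 2),
                      phase = rep(c("G1", "G2/M"), 2),
                      alpha = 1:4, beta = 5:8, lam = 1, gamma = 0,
                      qc_pass = c(TRUE, TRUE, TRUE, FALSE))
    m <- parameterMatrix(est)
    expect_identical(rownames(m), "A")   # B fails QC in one phase
    expect_identical(colnames(m),
                     c("alpha.G1", "beta.G1", "lam.G1", "gamma.G1",
                       "alpha.G2/M", "beta.G2/M", "lam.G2/M", "gamma.G2/M"))
    expect_equal(m["A", "beta.G2/M"], 6)
})

test_that("two separated blobs are recovered as exactly two clusters", {
    fx <- twoBlobs(61)
    z <- zscoreParameters(fx$m)
    cl <- clusterKinetics(z, kNeighbors = 20, seed = 61)
    expect_identical(length(unique(cl)), 2L)
    expect_equal(clusterAgreement(cl, fx$truth), 1.0)
})

test_that("clustering is invariant to gene order and collapses duplicates", {
    fx <- twoBlobs(62)
    z <- zscoreParameters(fx$m)
    cl <- clusterKinetics(z, seed = 63)
    perm <- sample(nrow(z))
    clp <- clusterKinetics(z[perm, ], seed = 63)
    # same partition up to label names
    expect_equal(clusterAgreement(clp, cl[rownames(z)[perm]]), 1.0)
    zsame <- matrix(0, 30, 4, dimnames = list(sprintf("g%d", 1:30), NULL))
    expect_identical(unname(clusterKinetics(zsame, kNeighbors = 5)),
                     rep(1L, 30))
})

test_that("covariation finds shared factors and respects the fixed order", {
    set.seed(64)
    nCells <- 500
    f <- rexp(nCells, 1)   # shared cell-level scaling factor
    mk <- function(idx) {
        m <- rbind(A = rpois(length(idx), 20 * f[idx]),
                   B = rpois(length(idx), 15 * f[idx]),
                   C = rpois(length(idx), 10),
                   D = rpois(length(idx), 10))
        m
    }
    byTime <- list(`0` = mk(1:125), `2` = mk(126:250),
                   `4` = mk(251:375), `6` = mk(376:500))
    cv <- covariationOverTime(byTime)
    expect_gt(cv$combined["A", "B"], 0.9)
    expect_lt(abs(cv$combined["C", "D"]), 0.1)
    for (m in cv$perTimepoint)
        expect_identical(rownames(m), cv$order)
    expect_equal(cv$combined, t(cv$combined))
    expect_equal(unname(diag(cv$combined)), rep(1, 4))
})

test_that("nucleocytoplasmic concatenation preserves totals", {
    nuc <- rbind(A = c(3, 0), B = c(1, 2))
    mid <- rbind(A = c(0, 4), B = c(2, 0))
    per <- rbind(A = c(0, 1), B = c(0, 1))
    cm <- toyCM(nuc, mid, per, timepoint_h = c(0, 2),
                volume_voxels = c(10, 10))
    nc <- buildNucleocytoplasmicMatrix(cm)
    expect_identical(dim(nc), c(2L, 4L))
    expect_equal(as.numeric(Matrix::rowSums(nc)),
                 as.numeric(Matrix::colSums(assay(cm, "total"))))
    # a fully nuclear gene has a zero _cyto entry
    expect_equal(nc[1, "A_cyto"], 0)
    expect_equal(nc[1, "A_nuc"], 3)
})

test_that("rank-sum comparison matches exhaustive enumeration", {
    est <- data.frame(gene = sprintf("g%d", 1:6), phase = "all",
                      alpha = 1, beta = c(1, 2, 3, 4, 5, 6), lam = 0,
                      gamma = 0, qc_pass = TRUE)
    lab <- setNames(rep(c("m6a", "non_m6a"), each = 3), est$gene)
    res <- compareGeneGroups(est, lab, "beta")
    # enumeration oracle: all C(6,3) assignments of ranks to group 1
    ranks <- 1:6
    obs <- sum(1:3)
    sums <- apply(combn(6, 3), 2, function(ix) sum(ranks[ix]))
    pExact <- mean(abs(sums - mean(range(sums))) >=
                   abs(obs - mean(range(sums))))
    expect_equal(res$p.value, pExact)
    expect_equal(res$p.value, 0.1)
    # label swap symmetry
    lab2 <- setNames(rep(c("non_m6a", "m6a"), each = 3), est$gene)
    expect_equal(compareGeneGroups(est, lab2, "beta")$p.value, res$p.value)
    expect_error(compareGeneGroups(est, setNames(rep("m6a", 6), est$gene),
                                   "beta"), "empty")
})
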