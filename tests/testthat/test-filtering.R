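test_that("residual p-values take the printed one-sided form", {
    d <- new("ResidualDistribution", gene = "g", mean = 2, sd = 1.5,
             nResiduals = 40L, replicates = 10L, degenerate = FALSE)
    expect_equal(residualPvalue(2, d), 0.5)   # center of a positive tail
    expect_equal(residualPvalue(2 + 1.96 * 1.5, d), 0.025,
                 tolerance = 1e-3)
    # lower tail if and only if the observed residual is negative
    expect_equal(residualPvalue(-1, d), pnorm(-1, 2, 1.5))
    expect_equal(residualPvalue(1, d), pnorm(1, 2, 1.5, lower.tail = FALSE))
    expect_equal(residualPvalue(0.3, c(0, 0.1)),
                 pnorm(0.3, 0, 0.1, lower.tail = FALSE))
    dd <- new("ResidualDistribution", gene = "g", mean = 0, sd = 0,
              nResiduals = 40L, replicates = 10L, degenerate = TRUE)
    expect_warning(p <- residualPvalue(5, dd), "degenerate")
    expect_equal(p, 1)
})

test_that("the threshold adapts to the number of genes", {
    expect_equal(adaptThreshold(1, 0.05), 0.05)
    expect_equal(adaptThreshold(200, 0.05), 2.5e-4)
    expect_lt(adaptThreshold(2000), adaptThreshold(200))
    expect_error(adaptThreshold(0), ">= 1")
    expect_error(adaptThreshold(10, 1.2), "in \\(0, 1\\)")
})

test_that("target reports are sorted, capped at 100 and order-invariant", {
    set.seed(11)
    p <- setNames(runif(300, 0, 1e-4), sprintf("g%03d", 1:300))
    rep1 <- rankTargets(p, threshold = 1e-3)
    expect_equal(nrow(reportEntries(rep1)), 100L)
    expect_true(rep1@capped)
    expect_false(is.unsorted(reportEntries(rep1)$p_value))
    # permuting the input order changes nothing
    rep2 <- rankTargets(p[sample(300)], threshold = 1e-3)
    expect_equal(reportEntries(rep2), reportEntries(rep1))
    # report entries are the head of the full table
    expect_equal(reportEntries(rep1),
                 head(reportTable(rep1)[, colnames(reportEntries(rep1))],
                      100))
    # no gene below threshold -> empty report
    rep3 <- rankTargets(p + 1e-2, threshold = 1e-3)
    expect_equal(nrow(reportEntries(rep3)), 0L)
    expect_false(rep3@capped)
})

test_that("bootstrap residual bookkeeping and degenerate path behave", {
    cpd <- linearCompendium(nDrivers = 6, nTargets = 10, nSamples = 30,
                            seed = 55)
    nTrain <- 30
    d <- bootstrapResiduals(cpd, "t01", nRounds = 5, nKeep = 10, seed = 1)
    expect_equal(d@nResiduals, 5L * (nTrain - round(0.6 * nTrain)))
    expect_equal(d@replicates, 5L)
    expect_false(d@degenerate)
    expect_gt(d@sd, 0)

    # a gene that is an exact affine copy of another: residuals collapse
    m <- exprValues(cpd)
    m <- rbind(m, copy = 2 * m["d01", ] + 1)
    cpd2 <- ExpressionCompendium(m)
    dcopy <- bootstrapResiduals(cpd2, "copy", nRounds = 3, nKeep = 5,
                                seed = 2)
    expect_true(dcopy@degenerate || dcopy@sd < 1e-6)
})

test_that("pooled residual scale is stable in the number of rounds", {
    cpd <- linearCompendium(nDrivers = 6, nTargets = 14, nSamples = 40,
                            seed = 77)
    d25 <- bootstrapResiduals(cpd, "t05", nRounds = 25, nKeep = 10, seed = 3)
    d50 <- bootstrapResiduals(cpd, "t05", nRounds = 50, nKeep = 10, seed = 4)
    expect_lt(abs(d25@sd - d50@sd) / d50@sd, 0.2)
})

test_that("identifyTargets flags the perturbed gene on a simulated network", {
    net <- simNet(30, seed = 21)
    dat <- simulateDataset(net, 50, seed = 22)
    dat <- injectPerturbation(dat, "exp_050", snr = 16, seed = 23)
    rep <- identifyTargets(dat, nRounds = 8, nKeep = 20, seed = 24)
    tab <- reportTable(rep)
    truth <- perturbedTruth(dat)[[1]]
    expect_equal(tab$gene[1], truth)                 # ranked first
    expect_lt(tab$p_value[1], 1e-6)                  # extremely low p
    expect_true(truth %in% reportEntries(rep)$gene)
    # reported p-values are reproduced by the one-sided normal formula
    # applied to the exposed residual distributions (z-score oracle)
    pUp <- pnorm(tab$residual, tab$res_mean, tab$res_sd, lower.tail = FALSE)
    pLo <- pnorm(tab$residual, tab$res_mean, tab$res_sd)
    pOracle <- ifelse(tab$res_sd > 0,
                      ifelse(tab$residual < 0, pLo, pUp), 1)
    expect_equal(tab$p_value, pOracle, tolerance = 1e-12)
    # determinism under a fixed seed
    rep2 <- identifyTargets(dat, nRounds = 8, nKeep = 20, seed = 24)
    expect_identical(reportTable(rep2), tab)
})

test_that("a treated sample identical to a training sample yields no calls", {
    net <- simNet(20, seed = 31)
    dat <- simulateDataset(net, 30, noiseFraction = 0,
                           bioNoiseFraction = 0, seed = 32)
    # the treated profile duplicates a training experiment exactly: its
    # residuals are ordinary model residuals, so nothing is reported
    m <- cbind(exprValues(dat), treated = exprValues(dat)[, "exp_007"])
    dup <- ExpressionCompendium(m, roles = c(rep("training", 30), "treated"))
    rep <- identifyTargets(dup, treated = "treated", nRounds = 4,
                           nKeep = 10, seed = 34)
    expect_equal(nrow(reportEntries(rep)), 0L)
})

test_that("ROC AUC equals the pairwise comparison oracle", {
    expect_equal(rocAUC(c(TRUE, TRUE, FALSE, FALSE),
                        c(1e-5, 1e-4, 0.2, 0.9)), 1)
    expect_equal(rocAUC(c(TRUE, FALSE, TRUE, FALSE), rep(0.5, 4)), 0.5)
    expect_error(rocAUC(c(TRUE, TRUE), c(0.1, 0.2)), "both a positive")
    bruteAUC <- function(lab, p) {
        pos <- p[lab]; neg <- p[!lab]
        tot <- 0
        for (a in pos) for (b in neg)
            tot <- tot + (a < b) + 0.5 * (a == b)
        tot / (length(pos) * length(neg))
    }
    set.seed(12)
    for (i in 1:25) {
        n <- sample(5:30, 1)
        lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (!any(lab) || all(lab)) next
        p <- round(runif(n), 2)   # rounded: exercises ties
        expect_equal(rocAUC(lab, p), bruteAUC(lab, p))
    }
})
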