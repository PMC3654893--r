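test_that("regulation factor has the Hill form and boundary behavior", {
    expect_equal(regulationFactor(1, K = 1, n = 3), 0.5)
    expect_equal(regulationFactor(7, K = 7, n = 1, "repression"), 0.5)
    expect_equal(regulationFactor(0, K = 2, n = 2, "activation"), 0)
    expect_equal(regulationFactor(0, K = 2, n = 2, "repression"), 1)
    expect_equal(regulationFactor(2, K = 1, n = 2, "activation"), 0.8)
    x <- seq(0, 10, by = 0.25)
    act <- regulationFactor(x, K = 3, n = 2, "activation")
    rep <- regulationFactor(x, K = 3, n = 2, "repression")
    expect_true(all(diff(act) > 0) && all(diff(rep) < 0))
    expect_true(all(act >= 0 & act <= 1 & rep >= 0 & rep <= 1))
    expect_error(regulationFactor(-1, 1, 1), "must be >= 0")
})

test_that("subnetwork sampling returns the requested size with induced edges", {
    tpl <- defaultTemplate(300)
    sub <- sampleSubnetwork(tpl, 50, seed = 3)
    expect_length(networkNodes(sub), 50)
    # induced-edge property: exactly the source edges among retained nodes
    keep <- networkNodes(sub)
    src <- networkEdges(tpl)
    induced <- src[src$regulator %in% keep & src$target %in% keep, 1:3]
    got <- networkEdges(sub)[, 1:3]
    expect_equal(got[order(got$regulator, got$target), ],
                 induced[order(induced$regulator, induced$target), ],
                 ignore_attr = TRUE)
    expect_error(sampleSubnetwork(tpl, 301), "between 1 and")
})

test_that("subnetwork growth only adds nodes connected to the current set", {
    chain <- RegulatoryNetwork(data.frame(
        regulator = c("a", "b", "c", "d"), target = c("b", "c", "d", "e"),
        sign = "activation"))
    for (s in 1:10) {
        sub <- sampleSubnetwork(chain, 3, seed = s)
        ord <- sub@metadata$additionOrder
        isSeed <- sub@metadata$seedNodes
        e <- networkEdges(chain)
        nbr <- function(v) unique(c(e$target[e$regulator == v],
                                    e$regulator[e$target == v]))
        for (k in seq_along(ord)[-1]) {
            if (isSeed[k]) next
            expect_true(length(intersect(nbr(ord[k]), ord[seq_len(k - 1)]))
                        >= 1)
        }
    }
    # identity case: requesting every node returns the whole network
    all5 <- sampleSubnetwork(chain, 5, seed = 1)
    expect_setequal(networkNodes(all5), networkNodes(chain))
    expect_equal(nrow(networkEdges(all5)), 4)
})

test_that("kinetics assignment covers regulated genes and draws from the sets", {
    chain <- RegulatoryNetwork(data.frame(regulator = "a", target = "b",
                                          sign = "activation"))
    net <- assignKinetics(chain, seed = 1)
    kin <- networkKinetics(net)
    expect_equal(kin$gene, "b")          # input gene a carries no kinetics
    expect_true(kin$vmax %in% c(5, 10, 20))
    expect_true(kin$basal %in% (kin$vmax * c(0.2, 0.5)))
    e <- networkEdges(net)
    expect_false(anyNA(e$K) || anyNA(e$hillN))

    big <- assignKinetics(sampleSubnetwork(defaultTemplate(300), 200,
                                           seed = 2), seed = 3)
    expect_true(all(networkEdges(big)$hillN %in% c(1L, 2L, 4L)))
    expect_true(all(networkEdges(big)$K > 0))
    # closed support for the K multiplier relative to the regulator scale
    kin <- networkKinetics(big)
    scale <- setNames(rep(5, length(networkNodes(big))), networkNodes(big))
    scale[kin$gene] <- kin$basal + kin$vmax / 2
    mult <- networkEdges(big)$K / scale[networkEdges(big)$regulator]
    expect_true(all(vapply(mult, function(m)
        any(abs(m - c(0.25, 0.5, 1, 2)) < 1e-9), logical(1))))

    twice1 <- assignKinetics(chain, seed = 42)
    twice2 <- assignKinetics(chain, seed = 42)
    expect_identical(networkEdges(twice1), networkEdges(twice2))
    expect_identical(networkKinetics(twice1), networkKinetics(twice2))
})

test_that("steady state follows the transition functions in cascade", {
    net <- cascadeNet(Kab = 2, Kbc = 3, nAb = 1L, nBc = 2L)
    # a at half-saturation of the a->b edge: b = 0 + 10 * 0.5 = 5
    x <- computeSteadyState(net, c(a = 2))
    expect_equal(x[["b"]], 5)
    # c = 10 * 5^2 / (3^2 + 5^2) evaluated in topological order
    expect_equal(x[["c"]], 10 * 25 / 34)
    expect_error(computeSteadyState(net, c(a = 1, b = 2)),
                 "exactly the input genes")
})

test_that("steady state is invariant to node ordering on acyclic nets", {
    net <- simNet(25, seed = 7)
    inputs <- inputGenes(net)
    lev <- setNames(runif(length(inputs), 2, 8), inputs)
    x1 <- computeSteadyState(net, lev)
    # same network with shuffled node and edge order
    set.seed(1)
    shuf <- net
    shuf@nodes <- sample(net@nodes)
    shuf@edges <- net@edges[sample(nrow(net@edges)), ]
    shuf@kinetics <- net@kinetics[sample(nrow(net@kinetics)), ]
    x2 <- computeSteadyState(shuf, lev)
    expect_equal(x2[names(x1)], x1, tolerance = 1e-10)
})

test_that("cyclic components reach a consistent fixed point", {
    net <- makeNet(
        data.frame(regulator = c("u", "a", "b"), target = c("a", "b", "a"),
                   sign = c("activation", "activation", "repression"),
                   K = c(2, 4, 3), hillN = c(1L, 2L, 1L),
                   stringsAsFactors = FALSE),
        data.frame(gene = c("a", "b"), vmax = c(10, 8), basal = c(1, 0.5),
                   stringsAsFactors = FALSE))
    x <- computeSteadyState(net, c(u = 2))
    # the fixed point satisfies both transition functions
    aExp <- 1 + 10 * regulationFactor(2, 2, 1) *
        regulationFactor(x[["b"]], 3, 1, "repression")
    bExp <- 0.5 + 8 * regulationFactor(x[["a"]], 4, 2)
    expect_equal(x[["a"]], aExp, tolerance = 1e-6)
    expect_equal(x[["b"]], bExp, tolerance = 1e-6)
})

test_that("noiseless simulation with fixed inputs is column-constant and reproducible", {
    net <- simNet(20, seed = 5)
    d1 <- simulateDataset(net, 10, noiseFraction = 0, bioNoiseFraction = 0,
                          inputRange = c(1, 1), seed = 9)
    v <- exprValues(d1)
    expect_true(all(abs(v - v[, 1]) < 1e-12))
    d2 <- simulateDataset(net, 10, noiseFraction = 0, bioNoiseFraction = 0,
                          inputRange = c(1, 1), seed = 9)
    expect_identical(exprValues(d1), exprValues(d2))
})

test_that("simulated datasets have the requested shape and positive values", {
    net <- simNet(20, seed = 6)
    dat <- simulateDataset(net, 100, seed = 10)
    expect_equal(dim(exprValues(dat)), c(20L, 100L))
    expect_true(all(exprValues(dat) > 0))
    expect_true(all(sampleRoles(dat) == "training"))
})

test_that("experimental noise magnitude is calibrated to the noise fraction", {
    set.seed(123)
    clean <- rep(50, 2e4)
    noisy <- addLognormalNoise(clean, 0.10)
    rel <- abs(noisy - clean) / clean
    se <- sd(rel) / sqrt(length(rel))
    expect_lt(abs(mean(rel) - 0.10), 3 * se)
})

test_that("perturbation changes exactly one cell by snr x noise x value", {
    net <- simNet(20, seed = 8)
    dat <- simulateDataset(net, 10, seed = 12)
    v0 <- exprValues(dat)
    pert <- injectPerturbation(dat, "exp_005", snr = 16, seed = 13)
    v1 <- exprValues(pert)
    diff <- v1 != v0
    expect_equal(sum(diff), 1L)                      # L0 difference is 1
    g <- perturbedTruth(pert)[["exp_005"]]
    expect_true(diff[g, "exp_005"])
    expect_equal(abs(v1[g, "exp_005"] - v0[g, "exp_005"]),
                 1.6 * v0[g, "exp_005"])             # snr 16 at 10% noise
    expect_equal(sampleRoles(pert)[["exp_005"]], "treated")

    # direct arithmetic at snr 4 on a known value
    m <- matrix(c(100, 3, 7, 9), 2, 2,
                dimnames = list(c("gA", "gB"), c("s1", "s2")))
    p4 <- injectPerturbation(ExpressionCompendium(m), "s1", snr = 4,
                             gene = "gA", seed = 2)
    expect_equal(abs(exprValues(p4)["gA", "s1"] - 100), 40)

    # zero-magnitude perturbation leaves values untouched, truth recorded
    p0 <- injectPerturbation(dat, "exp_002", snr = 0, seed = 3)
    expect_identical(exprValues(p0), v0)
    expect_length(perturbedTruth(p0), 1L)
})
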