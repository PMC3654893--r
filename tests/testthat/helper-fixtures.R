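# Fixture builders shared across the test files.  Everything is generated
# in code; no data files.

# hand-built network with explicit kinetics, for closed-form checks
makeNet <- function(edges, kinetics) {
    net <- RegulatoryNetwork(edges)
    net@kinetics <- kinetics
    methods::validObject(net)
    net
}

# a -> b -> c cascade, all activation, explicit parameters
cascadeNet <- function(Kab = 2, Kbc = 3, nAb = 1L, nBc = 2L,
                       vmaxB = 10, vmaxC = 10, basalB = 0, basalC = 0) {
    makeNet(
        data.frame(regulator = c("a", "b"), target = c("b", "c"),
                   sign = "activation", K = c(Kab, Kbc),
                   hillN = c(nAb, nBc), stringsAsFactors = FALSE),
        data.frame(gene = c("b", "c"), vmax = c(vmaxB, vmaxC),
                   basal = c(basalB, basalC), stringsAsFactors = FALSE))
}

# small kinetics-assigned subnetwork of the built-in template
simNet <- function(nGenes = 30, seed = 11) {
    assignKinetics(sampleSubnetwork(defaultTemplate(300), nGenes,
                                    seed = seed), seed = seed + 1)
}

# compendium whose genes are exact linear functions of a few driver
# genes plus gaussian noise: the SVR model class is correct, so
# out-of-sample residuals are honestly normal ("noiseless model")
linearCompendium <- function(nDrivers = 20, nTargets = 80, nSamples = 60,
                             noiseSd = 0.2, seed = 101) {
    set.seed(seed)
    D <- matrix(runif(nDrivers * nSamples, 2, 10), nDrivers,
                dimnames = list(sprintf("d%02d", seq_len(nDrivers)),
                                sprintf("s%03d", seq_len(nSamples))))
    Tm <- matrix(NA_real_, nTargets, nSamples,
                 dimnames = list(sprintf("t%02d", seq_len(nTargets)),
                                 colnames(D)))
    for (i in seq_len(nTargets)) {
        drv <- sample(nDrivers, 2)
        w <- runif(2, 0.3, 1)
        Tm[i, ] <- 5 + w[1] * D[drv[1], ] + w[2] * D[drv[2], ] +
            rnorm(nSamples, 0, noiseSd)
    }
    ExpressionCompendium(rbind(D, Tm))
}

# toy three-level ontology over 20 genes used by the enrichment tests
toyOntology <- function() {
    genes <- sprintf("g%02d", 1:20)
    ann <- data.frame(
        gene = c(genes[1:4],          # leafA
                 genes[5:8],          # leafB
                 genes[9:12],         # midOther
                 genes[13:20]),       # broad background term
        term = c(rep("leafA", 4), rep("leafB", 4), rep("midOther", 4),
                 rep("bg", 8)),
        stringsAsFactors = FALSE)
    graph <- data.frame(
        child = c("leafA", "leafB", "midAB", "midOther"),
        parent = c("midAB", "midAB", "root", "root"),
        stringsAsFactors = FALSE)
    list(genes = genes, ann = ann, graph = graph)
}
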