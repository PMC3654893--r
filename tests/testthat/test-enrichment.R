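test_that("hypergeometric p-values match exact enumeration", {
    # P(X >= 2) for N=10, K=3, n=5: (C(3,2)C(7,3) + C(3,3)C(7,2)) / C(10,5)
    expect_equal(hypergeomPvalue(2, 3, 5, 10), 0.5)
    expect_equal(hypergeomPvalue(0, 3, 5, 10), 1)        # P(X >= 0)
    expect_equal(hypergeomPvalue(5, 10, 5, 10), 1)       # K = N forced draw
    expect_error(hypergeomPvalue(4, 3, 5, 10), "inconsistent")
    expect_error(hypergeomPvalue(2, 11, 5, 10), "inconsistent")

    enumP <- function(k, K, n, N, dir) {
        j <- 0:min(n, K)
        pj <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
        if (dir == "over") sum(pj[j >= k]) else sum(pj[j <= k])
    }
    set.seed(13)
    for (i in 1:50) {
        N <- sample(2:15, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
        k <- sample(0:min(n, K), 1)
        expect_equal(hypergeomPvalue(k, K, n, N, "over"),
                     enumP(k, K, n, N, "over"), tolerance = 1e-12)
        expect_equal(hypergeomPvalue(k, K, n, N, "under"),
                     enumP(k, K, n, N, "under"), tolerance = 1e-12)
        # the two tails share the P(X = k) atom
        expect_gte(hypergeomPvalue(k, K, n, N, "over") +
                   hypergeomPvalue(k, K, n, N, "under"), 1 - 1e-12)
    }
})

test_that("a flat hierarchy reduces to independent hypergeometric tests", {
    ont <- toyOntology()
    hits <- ont$genes[c(1:4, 5)]
    res <- conditionalEnrichment(hits, ont$ann, graph = NULL, cutoff = 1)
    full <- attr(res, "fullResults")
    for (i in seq_len(nrow(full))) {
        tg <- ont$ann$gene[ont$ann$term == full$term[i]]
        expect_equal(full$p_value[i],
                     hypergeomPvalue(length(intersect(tg, hits)),
                                     length(tg), length(hits), 20))
    }
})

test_that("parents significant only through a significant child are conditioned away", {
    ont <- toyOntology()
    # all four leafA genes reported: leafA is strongly enriched; its parent
    # midAB receives hits only via leafA (leafB contributes none)
    hits <- ont$genes[1:4]
    res <- conditionalEnrichment(hits, ont$ann, ont$graph, cutoff = 0.05)
    expect_true("leafA" %in% res$term)
    expect_false("midAB" %in% res$term)
    full <- attr(res, "fullResults")
    # unconditional run: midAB would be significant
    unc <- attr(conditionalEnrichment(hits, ont$ann, ont$graph,
                                      cutoff = 1e-12), "fullResults")
    pUnc <- unc$p_value[unc$term == "midAB"]
    pCond <- full$p_value[full$term == "midAB"]
    expect_lt(pUnc, 0.05)
    expect_gte(pCond, pUnc)   # removal can only weaken the evidence
})

test_that("conditional p-values match a hand-simulated leaves-first pass", {
    ont <- toyOntology()
    hits <- ont$genes[c(1:4, 9, 13)]
    cutoff <- 0.05
    res <- conditionalEnrichment(hits, ont$ann, ont$graph, cutoff = cutoff)
    full <- attr(res, "fullResults")

    # manual trace: propagate annotations, then test leaves upward
    termGenes <- split(ont$ann$gene, ont$ann$term)
    termGenes$midAB <- unique(c(termGenes$leafA, termGenes$leafB))
    termGenes$root <- unique(c(termGenes$midAB, termGenes$midOther))
    universe <- unique(ont$ann$gene)
    N <- length(universe); n <- length(hits)
    pOf <- function(g) hypergeomPvalue(length(intersect(g, hits)),
                                       length(g), n, N)
    pLeafA <- pOf(termGenes$leafA)
    pLeafB <- pOf(termGenes$leafB)
    pMidOther <- pOf(termGenes$midOther)
    midABGenes <- termGenes$midAB
    if (pLeafA <= cutoff) midABGenes <- setdiff(midABGenes, termGenes$leafA)
    if (pLeafB <= cutoff) midABGenes <- setdiff(midABGenes, termGenes$leafB)
    pMidAB <- pOf(midABGenes)
    rootGenes <- termGenes$root
    if (pMidAB <= cutoff) rootGenes <- setdiff(rootGenes, termGenes$midAB)
    if (pMidOther <= cutoff)
        rootGenes <- setdiff(rootGenes, termGenes$midOther)
    pRoot <- pOf(rootGenes)
    want <- c(leafA = pLeafA, leafB = pLeafB, midAB = pMidAB,
              midOther = pMidOther, root = pRoot)
    got <- setNames(full$p_value, full$term)[names(want)]
    expect_equal(got, want, tolerance = 1e-12)
})

test_that("enrichment inputs are validated", {
    ont <- toyOntology()
    cyc <- data.frame(child = c("a", "b"), parent = c("b", "a"))
    expect_error(conditionalEnrichment(ont$genes[1:3], ont$ann, cyc),
                 "acyclic")
    expect_warning(conditionalEnrichment(c(ont$genes[1:3], "nope"),
                                         ont$ann, cutoff = 1),
                   "outside the annotated universe")
})

test_that("annotation and term-graph readers parse both accepted formats", {
    ann <- tempfile(fileext = ".tsv")
    writeLines(c("# comment", "g1\tT1", "g1\tT2", "g2\tT1"), ann)
    tab <- readAnnotations(ann)
    expect_equal(nrow(tab), 3)
    expect_setequal(tab$gene, c("g1", "g2"))

    gaf <- tempfile(fileext = ".gaf")
    writeLines(c("!gaf-version: 2.2",
                 paste("DB", "ID1", "CDC42", "", "GO:0001", "", "", "",
                       sep = "\t"),
                 paste("DB", "ID2", "AUR1", "", "GO:0002", "", "", "",
                       sep = "\t")), gaf)
    tg <- readAnnotations(gaf)
    expect_equal(tg$gene, c("CDC42", "AUR1"))
    expect_equal(tg$term, c("GO:0001", "GO:0002"))

    obo <- tempfile(fileext = ".obo")
    writeLines(c("format-version: 1.2", "", "[Term]", "id: GO:0002",
                 "name: child", "is_a: GO:0001 ! parent", "", "[Term]",
                 "id: GO:0001", "name: parent"), obo)
    gr <- readTermGraph(obo)
    expect_equal(gr, data.frame(child = "GO:0002", parent = "GO:0001",
                                stringsAsFactors = FALSE))

    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("T2\tT1", "T3\tT1"), tsv)
    expect_equal(readTermGraph(tsv)$parent, c("T1", "T1"))
})
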