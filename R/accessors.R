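#' @rdname ExpressionCompendium
#' @param x an `ExpressionCompendium`.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @rdname ExpressionCompendium
#' @export
sampleRoles <- function(x)
    setNames(SummarizedExperiment::colData(x)$role, colnames(x))

#' @rdname ExpressionCompendium
#' @export
trainingSamples <- function(x) colnames(x)[sampleRoles(x) == "training"]

#' @rdname ExpressionCompendium
#' @export
treatedSamples <- function(x) colnames(x)[sampleRoles(x) == "treated"]

#' @rdname ExpressionCompendium
#' @details `perturbedTruth()` returns the named character vector of
#'   simulation truth (perturbed gene per treated sample), `NA`-free.
#' @export
perturbedTruth <- function(x) {
    truth <- setNames(SummarizedExperiment::colData(x)$perturbedGene,
                      colnames(x))
    truth[!is.na(truth)]
}

setMethod("show", "ExpressionCompendium", function(object) {
    cat("ExpressionCompendium:", nrow(object), "genes x", ncol(object),
        "samples\n")
    r <- sampleRoles(object)
    cat("  training:", sum(r == "training"),
        " treated:", sum(r == "treated"), "\n")
    tr <- perturbedTruth(object)
    if (length(tr))
        cat("  perturbation truth recorded for",
            length(tr), "sample(s)\n")
})

#' @rdname RegulatoryNetwork
#' @param net a `RegulatoryNetwork`.
#' @export
networkNodes <- function(net) net@nodes

#' @rdname RegulatoryNetwork
#' @export
networkEdges <- function(net) net@edges

#' @rdname RegulatoryNetwork
#' @details `inputGenes()` returns the in-degree-0 node set, i.e. the genes
#'   whose expression is set by external conditions rather than computed
#'   from a regulation function.
#' @export
inputGenes <- function(net)
    setdiff(net@nodes, unique(net@edges$target))

#' @rdname RegulatoryNetwork
#' @export
networkKinetics <- function(net) net@kinetics

setMethod("show", "RegulatoryNetwork", function(object) {
    cat("RegulatoryNetwork:", length(object@nodes), "genes,",
        nrow(object@edges), "edges\n")
    cat("  input genes:", length(inputGenes(object)), "\n")
    cat("  kinetics:",
        if (nrow(object@kinetics)) "assigned" else "not assigned", "\n")
})

#' @rdname TargetReport
#' @param report a `TargetReport`.
#' @export
reportEntries <- function(report) report@entries

#' @rdname TargetReport
#' @details `reportTable()` returns the full per-gene table (all genes, not
#'   only those below the threshold), used to build ROC curves.
#' @export
reportTable <- function(report) report@fullTable

#' @rdname TargetReport
#' @export
reportThreshold <- function(report) report@threshold

setMethod("show", "TargetReport", function(object) {
    cat("TargetReport:", nrow(object@entries), "candidate gene(s) at p <=",
        format(object@threshold, digits = 3),
        if (object@capped) "(capped at 100)" else "", "\n")
    if (nrow(object@entries))
        print(head(object@entries, 10), row.names = FALSE)
})

setMethod("show", "ResidualDistribution", function(object) {
    cat("ResidualDistribution for", object@gene, ": mean",
        format(object@mean, digits = 4), ", sd",
        format(object@sd, digits = 4), "(", object@nResiduals,
        "residuals over", object@replicates, "rounds",
        if (object@degenerate) "; degenerate" else "", ")\n")
})

setMethod("show", "GeneModel", function(object) {
    cat("GeneModel for", object@targetGene, "with",
        length(object@regressors), "regressor(s)",
        if (is.null(object@fit)) "(constant fallback)" else "", "\n")
})

setMethod("show", "FeatureSubset", function(object) {
    cat("FeatureSubset for", object@targetGene, ":",
        length(object@members), "member(s), merit",
        format(object@merit, digits = 4), "\n")
})
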