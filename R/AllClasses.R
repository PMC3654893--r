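#' @import methods
#' @importFrom stats cor pnorm phyper quantile rnorm runif sd rlnorm setNames
#'   p.adjust predict
#' @importFrom utils read.delim write.table packageVersion head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @useDynLib netfilter, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Expression compendium container
#'
#' A genes-by-samples matrix of raw positive intensities together with a
#' per-sample role (`"training"` or `"treated"`) and, for simulated data,
#' the identity of the perturbed gene in each treated sample.  Extends
#' [SummarizedExperiment::SummarizedExperiment] with the intensities in the
#' `"exprs"` assay and `role` / `perturbedGene` columns in `colData`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [ExpressionCompendium()] for the constructor, [exprValues()],
#'   [sampleRoles()], [perturbedTruth()].
#' @export
setClass("ExpressionCompendium", contains = "SummarizedExperiment")

setValidity("ExpressionCompendium", function(object) {
    msg <- character(0)
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        v <- SummarizedExperiment::assay(object, "exprs")
        if (any(!is.finite(v)) || any(v <= 0))
            msg <- c(msg, "all expression values must be finite and > 0")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    if (!"role" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'role' column")
    else if (!all(cd$role %in% c("training", "treated")))
        msg <- c(msg, "sample roles must be 'training' or 'treated'")
    if (length(msg)) msg else TRUE
})

#' Construct an expression compendium
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids); raw positive intensities.
#' @param roles character vector, one of `"training"`/`"treated"` per sample.
#'   Defaults to all-training.
#' @param perturbedGene named character vector mapping treated sample ids to
#'   the identifier of the gene perturbed in that sample (simulation truth);
#'   samples not named are recorded as `NA`.
#' @return An [ExpressionCompendium-class] object.
#' @examples
#' m <- matrix(1:6 + 0.5, 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' cpd <- ExpressionCompendium(m)
#' exprValues(cpd)
#' @export
ExpressionCompendium <- function(values,
                                 roles = rep("training", ncol(values)),
                                 perturbedGene = character(0)) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        stop("'values' must have gene identifiers as rownames")
    if (is.null(colnames(values)))
        stop("'values' must have sample identifiers as colnames")
    truth <- rep(NA_character_, ncol(values))
    names(truth) <- colnames(values)
    if (length(perturbedGene))
        truth[names(perturbedGene)] <- perturbedGene
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(role = roles, perturbedGene = truth,
                                       row.names = colnames(values)))
    methods::new("ExpressionCompendium", se)
}

#' Directed regulatory network with kinetic parameters
#'
#' Nodes are genes; edges are signed (activation/repression) regulator to
#' target interactions.  After [assignKinetics()] every regulated node
#' carries a maximal transcription rate (`vmax`) and basal level, and every
#' edge a half-saturation constant `K` and integer Hill coefficient.
#' Genes without incoming edges are the network's input genes: their levels
#' are set externally per experiment rather than computed.
#'
#' @slot nodes character vector of gene identifiers.
#' @slot edges data.frame with columns `regulator`, `target`,
#'   `sign` (`"activation"`/`"repression"`), `K`, `hillN` (the latter two
#'   `NA` until kinetics are assigned).
#' @slot kinetics data.frame with columns `gene`, `vmax`, `basal` for
#'   regulated (non-input) genes; zero rows until kinetics are assigned.
#' @slot metadata list; records the subnetwork growth trace
#'   (`additionOrder`, `seedNodes`) when produced by [sampleSubnetwork()].
#' @export
setClass("RegulatoryNetwork",
    representation(nodes = "character", edges = "data.frame",
                   kinetics = "data.frame", metadata = "list"),
    prototype(nodes = character(0),
              edges = data.frame(regulator = character(0),
                                 target = character(0),
                                 sign = character(0),
                                 K = numeric(0), hillN = integer(0),
                                 stringsAsFactors = FALSE),
              kinetics = data.frame(gene = character(0), vmax = numeric(0),
                                    basal = numeric(0),
                                    stringsAsFactors = FALSE),
              metadata = list()))

setValidity("RegulatoryNetwork", function(object) {
    msg <- character(0)
    e <- object@edges
    need <- c("regulator", "target", "sign")
    if (!all(need %in% colnames(e)))
        return("edges must have columns regulator, target, sign")
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "duplicate node identifiers")
    if (nrow(e)) {
        if (any(e$regulator == e$target))
            msg <- c(msg, "self-loop edges are not allowed")
        if (anyDuplicated(e[, c("regulator", "target")]))
            msg <- c(msg, "duplicate edges are not allowed")
        if (!all(c(e$regulator, e$target) %in% object@nodes))
            msg <- c(msg, "edge endpoints must be network nodes")
        if (!all(e$sign %in% c("activation", "repression")))
            msg <- c(msg, "edge sign must be 'activation' or 'repression'")
    }
    k <- object@kinetics
    if (nrow(k)) {
        if (any(k$vmax <= 0) || any(k$basal < 0))
            msg <- c(msg, "vmax must be > 0 and basal >= 0")
    }
    ke <- e$K[!is.na(e$K)]
    if (length(ke) && any(ke <= 0))
        msg <- c(msg, "edge half-saturation constants must be > 0")
    hn <- e$hillN[!is.na(e$hillN)]
    if (length(hn) && any(hn < 1))
        msg <- c(msg, "Hill coefficients must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a regulatory network from an edge list
#'
#' @param edges data.frame with columns `regulator`, `target`, `sign`
#'   (`"activation"`/`"repression"`, or `"+"`/`"-"`); optional `K`, `hillN`.
#' @param nodes optional character vector of node ids (defaults to the union
#'   of edge endpoints; supply explicitly to keep isolated genes).
#' @return A [RegulatoryNetwork-class].
#' @export
RegulatoryNetwork <- function(edges, nodes = NULL) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    edges$sign <- c("+" = "activation", "-" = "repression",
                    activation = "activation",
                    repression = "repression")[as.character(edges$sign)]
    if (is.null(edges$K)) edges$K <- NA_real_
    if (is.null(edges$hillN)) edges$hillN <- NA_integer_
    if (is.null(nodes))
        nodes <- unique(c(edges$regulator, edges$target))
    methods::new("RegulatoryNetwork", nodes = as.character(nodes),
                 edges = edges[, c("regulator", "target", "sign",
                                   "K", "hillN")],
                 kinetics = data.frame(gene = character(0),
                                       vmax = numeric(0), basal = numeric(0),
                                       stringsAsFactors = FALSE),
                 metadata = list())
}

#' Per-gene fitted regression model
#'
#' Holds the selected regressor genes, the z-score normalization learned on
#' the training split, and the fitted epsilon-SVR state (or a constant
#' fallback when no informative regressor exists).
#'
#' @slot targetGene target gene identifier.
#' @slot regressors character vector of regressor gene identifiers.
#' @slot center,scale,yCenter,yScale normalization statistics.
#' @slot fit the underlying [e1071::svm] fit, or `NULL` for a constant model.
#' @slot constant numeric; prediction of the constant fallback model.
#' @slot hyperparams named list (cost, tolerance, epsilon).
#' @export
setClass("GeneModel",
    representation(targetGene = "character", regressors = "character",
                   center = "numeric", scale = "numeric",
                   yCenter = "numeric", yScale = "numeric",
                   fit = "ANY", constant = "numeric",
                   hyperparams = "list"))

#' Bootstrap residual distribution for one gene
#'
#' Location and scale of pooled out-of-sample residuals (observed minus
#' predicted) over repeated 60/40 train/test splits, summarized as a normal
#' density.
#'
#' @slot gene gene identifier.
#' @slot mean,sd residual location and scale.
#' @slot nResiduals pooled residual count.
#' @slot replicates number of bootstrap rounds.
#' @slot degenerate `TRUE` when the residual scale collapsed to zero (the
#'   gene's p-value is then reported as 1: the model cannot assess it).
#' @export
setClass("ResidualDistribution",
    representation(gene = "character", mean = "numeric", sd = "numeric",
                   nResiduals = "integer", replicates = "integer",
                   degenerate = "logical"))

setValidity("ResidualDistribution", function(object) {
    msg <- character(0)
    if (length(object@sd) && (is.na(object@sd) || object@sd < 0))
        msg <- c(msg, "sd must be >= 0")
    if (length(object@nResiduals) && object@nResiduals < 2)
        msg <- c(msg, "at least 2 pooled residuals are required")
    if (length(msg)) msg else TRUE
})

#' Ranked report of candidate perturbed genes
#'
#' @slot entries data.frame with columns `rank`, `gene`, `residual`,
#'   `p_value`, sorted by ascending p-value, truncated to at most 100 rows.
#' @slot threshold the applied p-value cutoff.
#' @slot capped whether the 100-gene cap was applied.
#' @slot fullTable data.frame with the per-gene residuals and p-values for
#'   every gene (used for ROC evaluation).
#' @export
setClass("TargetReport",
    representation(entries = "data.frame", threshold = "numeric",
                   capped = "logical", fullTable = "data.frame"))

setValidity("TargetReport", function(object) {
    msg <- character(0)
    e <- object@entries
    if (nrow(e) > 100)
        msg <- c(msg, "a report holds at most 100 entries")
    if (nrow(e) && is.unsorted(e$p_value))
        msg <- c(msg, "entries must be sorted by ascending p-value")
    if (nrow(e) && any(e$p_value > object@threshold))
        msg <- c(msg, "all reported p-values must be <= threshold")
    if (length(msg)) msg else TRUE
})

#' Feature subset selected for one target gene
#'
#' @slot targetGene target gene identifier.
#' @slot members ordered regressor gene identifiers (order of acceptance).
#' @slot merit the CFS merit of the subset.
#' @export
setClass("FeatureSubset",
    representation(targetGene = "character", members = "character",
                   merit = "numeric"))

setValidity("FeatureSubset", function(object) {
    msg <- character(0)
    if (object@targetGene %in% object@members)
        msg <- c(msg, "the target gene cannot be its own regressor")
    if (anyDuplicated(object@members))
        msg <- c(msg, "subset members must be unique")
    if (length(msg)) msg else TRUE
})
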