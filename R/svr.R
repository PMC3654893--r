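# Per-gene epsilon support-vector regression with fixed hyper-parameters:
# complexity C = 0.8, tolerance 0.001, tube width epsilon = 1e-12,
# first-order (linear) polynomial kernel, z-score normalization learned on
# the training split.  The optimizer is libsvm's SMO (via e1071); the
# contract is the epsilon-SVR optimum, not the particular solver.

#' Train a per-gene epsilon-SVR model
#'
#' Fits `y ~ f(X)` with an epsilon-insensitive support-vector regression
#' using a first-order polynomial (linear) kernel.  Features and target
#' are z-score normalized on the training data; predictions are
#' un-normalized before use.  Zero-variance features are dropped with a
#' warning; if every feature is degenerate (or the target is constant) a
#' constant model predicting `mean(y)` is returned.
#'
#' @param X numeric matrix, samples by regressors (colnames = gene ids).
#' @param y numeric target values, one per sample.
#' @param cost complexity parameter C (default 0.8).
#' @param tolerance SMO termination tolerance (default 0.001).
#' @param epsilon width of the insensitivity tube (default 1e-12, making
#'   the fit a near-interpolating regularized regression).
#' @param target target gene identifier (bookkeeping).
#' @return A [GeneModel-class].
#' @export
trainSVR <- function(X, y, cost = 0.8, tolerance = 0.001, epsilon = 1e-12,
                     target = NA_character_) {
    X <- as.matrix(X)
    if (nrow(X) < 2) stop("at least 2 samples are required")
    if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
    if (length(y) != nrow(X)) stop("'y' must have one value per row of X")
    if (is.null(colnames(X)))
        colnames(X) <- paste0("f", seq_len(ncol(X)))
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    keep <- is.finite(scl) & scl > 0
    if (!all(keep))
        warning("dropping zero-variance feature(s): ",
                paste(colnames(X)[!keep], collapse = ", "))
    yc <- mean(y)
    ys <- sd(y)
    hp <- list(cost = cost, tolerance = tolerance, epsilon = epsilon)
    if (!any(keep) || !is.finite(ys) || ys == 0) {
        return(methods::new("GeneModel", targetGene = as.character(target),
                            regressors = colnames(X)[keep],
                            center = ctr[keep], scale = scl[keep],
                            yCenter = yc, yScale = if (is.finite(ys)) ys else 0,
                            fit = NULL, constant = yc, hyperparams = hp))
    }
    Xs <- scale(X[, keep, drop = FALSE], center = ctr[keep],
                scale = scl[keep])
    fit <- e1071::svm(Xs, (y - yc) / ys, type = "eps-regression",
                      kernel = "linear", cost = cost, tolerance = tolerance,
                      epsilon = epsilon, scale = FALSE, fitted = FALSE)
    methods::new("GeneModel", targetGene = as.character(target),
                 regressors = colnames(X)[keep],
                 center = ctr[keep], scale = scl[keep],
                 yCenter = yc, yScale = ys,
                 fit = fit, constant = NA_real_, hyperparams = hp)
}

# prediction core: newX is samples x regressors in model order
.predictGeneModel <- function(model, newX) {
    if (is.null(model@fit))
        return(rep(model@constant, nrow(newX)))
    Xs <- scale(newX, center = model@center, scale = model@scale)
    as.numeric(predict(model@fit, Xs)) * model@yScale + model@yCenter
}

#' Predict expression with a fitted gene model
#'
#' Applies the stored normalization to the regressor values, evaluates
#' `f(x) = sum_i alpha_i K(x_i, x) + b`, and un-normalizes the result.
#'
#' @param object a [GeneModel-class].
#' @param newdata samples-by-regressors matrix (colnames covering the
#'   model's regressors) or a named vector for a single sample.
#' @param ... ignored.
#' @return Numeric predicted expression, one value per sample.
#' @export
setMethod("predict", "GeneModel", function(object, newdata, ...) {
    if (is.null(dim(newdata)))
        newdata <- matrix(newdata, 1, length(newdata),
                          dimnames = list(NULL, names(newdata)))
    if (length(object@regressors)) {
        missing <- setdiff(object@regressors, colnames(newdata))
        if (length(missing))
            stop("missing regressor value(s): ",
                 paste(missing, collapse = ", "))
        newdata <- newdata[, object@regressors, drop = FALSE]
    }
    .predictGeneModel(object, newdata)
})

# Dual objective of the trained epsilon-SVR on the normalized scale:
# W(beta) = -1/2 beta' K beta - epsilon * sum|beta| + beta' y
# with beta = alpha - alpha* (e1071's coefs) and K the linear kernel.
# Used by tests to compare against an independent QP solution.
.svrDualObjective <- function(model, X, y) {
    stopifnot(!is.null(model@fit))
    Xs <- scale(X[, model@regressors, drop = FALSE],
                center = model@center, scale = model@scale)
    ys <- (y - model@yCenter) / model@yScale
    beta <- as.numeric(model@fit$coefs)
    sv <- Xs[model@fit$index, , drop = FALSE]
    K <- tcrossprod(sv)
    as.numeric(-0.5 * t(beta) %*% K %*% beta -
               model@hyperparams$epsilon * sum(abs(beta)) +
               sum(beta * ys[model@fit$index]))
}

#' Save or load a set of fitted gene models
#'
#' Convenience serialization of a run's `gene id -> GeneModel` mapping.
#'
#' @param models named list of [GeneModel-class] objects.
#' @param path file path.
#' @return `loadGeneModels` returns the named list.
#' @export
saveGeneModels <- function(models, path) {
    saveRDS(list(format = "netfilter-genemodels",
                 version = as.character(utils::packageVersion("netfilter")),
                 models = models), path)
    invisible(path)
}

#' @rdname saveGeneModels
#' @export
loadGeneModels <- function(path) {
    obj <- readRDS(path)
    if (!identical(obj$format, "netfilter-genemodels"))
        stop("not a netfilter gene-model archive: ", path)
    obj$models
}
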