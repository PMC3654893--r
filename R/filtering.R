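# Core network-filtering pipeline: bootstrap residual distributions,
# one-sided normal p-values for the treated sample, adaptive threshold,
# ranked target report.

.pval <- function(observed, m, s) {
    if (!is.finite(s) || s <= 0) {
        warning("degenerate residual distribution (sd = 0); p-value set to 1")
        return(1)
    }
    pnorm(observed, m, s, lower.tail = observed < 0)
}

#' One-sided residual p-value
#'
#' Probability that a residual as extreme as the observed one arises from
#' the gene's bootstrap residual distribution: the lower normal tail when
#' the observed residual is negative, the upper tail otherwise (so small
#' p-values flag residuals inconsistent with the trained model in either
#' direction).
#'
#' @param observed the treated-sample residual (observed minus predicted).
#' @param dist a [ResidualDistribution-class], or a numeric vector
#'   `c(mean, sd)`.
#' @return p-value in `(0, 1]`; degenerate distributions (sd = 0) return 1
#'   with a warning.
#' @export
setGeneric("residualPvalue",
           function(observed, dist) standardGeneric("residualPvalue"))

#' @rdname residualPvalue
#' @export
setMethod("residualPvalue", signature(dist = "ResidualDistribution"),
    function(observed, dist) {
        if (dist@degenerate) {
            warning("degenerate residual distribution for ", dist@gene,
                    "; p-value set to 1")
            return(1)
        }
        .pval(observed, dist@mean, dist@sd)
    })

#' @rdname residualPvalue
#' @export
setMethod("residualPvalue", signature(dist = "numeric"),
    function(observed, dist) .pval(observed, dist[1], dist[2]))

#' Adaptive p-value threshold
#'
#' Bonferroni-style cutoff `alpha / nGenes`, adapting the per-gene
#' threshold to the number of genes tested so that the family-wise false
#' positive rate stays controlled at `alpha`.
#'
#' @param nGenes number of genes tested, `>= 1`.
#' @param alpha family error rate, in (0, 1) (default 0.05).
#' @return The p-value cutoff.
#' @export
adaptThreshold <- function(nGenes, alpha = 0.05) {
    if (nGenes < 1) stop("'nGenes' must be >= 1")
    if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
    alpha / nGenes
}

#' Build a ranked target report
#'
#' Genes with `p <= threshold` sorted by ascending p-value (ties broken by
#' gene identifier), truncated to the first 100 entries.
#'
#' @param pvalues named numeric vector of per-gene p-values.
#' @param threshold applied p-value cutoff.
#' @param residuals optional named numeric vector of treated-sample
#'   residuals (reported alongside).
#' @param cap maximum number of entries returned (default 100).
#' @return A [TargetReport-class]; its full table keeps all genes.
#' @export
rankTargets <- function(pvalues, threshold, residuals = NULL, cap = 100L) {
    genes <- names(pvalues)
    if (is.null(genes)) stop("'pvalues' must be a named vector")
    if (is.null(residuals))
        residuals <- setNames(rep(NA_real_, length(pvalues)), genes)
    ord <- order(pvalues, genes)
    full <- data.frame(rank = seq_along(ord), gene = genes[ord],
                       residual = as.numeric(residuals[genes[ord]]),
                       p_value = as.numeric(pvalues[ord]),
                       stringsAsFactors = FALSE)
    sel <- full[full$p_value <= threshold, , drop = FALSE]
    capped <- nrow(sel) > cap
    if (capped) sel <- sel[seq_len(cap), , drop = FALSE]
    rownames(sel) <- NULL
    methods::new("TargetReport", entries = sel,
                 threshold = as.numeric(threshold), capped = capped,
                 fullTable = full)
}

# lean fit + predict used inside the bootstrap loop: z-score
# normalization, eps-SVR with linear kernel, prediction via the explicit
# weight vector.  Xtr/Xte are samples x features; returns predictions on
# the original scale.
.fastFitPredict <- function(Xtr, ytr, Xte, cost, tolerance, epsilon) {
    n <- nrow(Xtr)
    ctr <- colMeans(Xtr)
    scl <- sqrt((colSums(Xtr * Xtr) - n * ctr^2) / (n - 1))
    keep <- is.finite(scl) & scl > 0
    yc <- mean(ytr)
    ys <- sd(ytr)
    if (!any(keep) || !is.finite(ys) || ys == 0)
        return(rep(yc, nrow(Xte)))
    Xs <- (Xtr[, keep, drop = FALSE] -
           rep(ctr[keep], each = n)) / rep(scl[keep], each = n)
    fit <- e1071::svm(Xs, (ytr - yc) / ys, type = "eps-regression",
                      kernel = "linear", cost = cost,
                      tolerance = tolerance, epsilon = epsilon,
                      scale = FALSE, fitted = FALSE)
    w <- crossprod(fit$SV, fit$coefs)
    m <- nrow(Xte)
    Xes <- (Xte[, keep, drop = FALSE] -
            rep(ctr[keep], each = m)) / rep(scl[keep], each = m)
    as.numeric(Xes %*% w - fit$rho) * ys + yc
}

# one bootstrap round / final fit for a set of genes on given training
# columns: per-gene IG ranking, CFS forward search, SVR fit, predictions
# on the evaluation columns.  Returns genes x eval-columns predictions.
.fitRound <- function(vals, trainCols, evalCols, nKeep, nBins, patience,
                      cost, tolerance, epsilon) {
    ids <- rownames(vals)
    G <- length(ids)
    Xtr <- vals[, trainCols, drop = FALSE]
    Xev <- vals[, evalCols, drop = FALSE]
    bins <- .discretizeRows(Xtr, nBins)
    ig <- ig_columns_cpp(bins, max(bins) + 1L, seq_len(G))
    cr <- .absCor(Xtr)
    pred <- matrix(NA_real_, G, length(evalCols),
                   dimnames = list(ids, evalCols))
    keepN <- min(nKeep, G - 1L)
    tXtr <- t(Xtr)
    tXev <- t(Xev)
    for (g in seq_len(G)) {
        sc <- ig[, g]
        sc[g] <- -Inf
        cand <- order(-sc, ids)[seq_len(keepN)]
        sel <- .cfsSearchIdx(cr[cand, g], cr[cand, cand, drop = FALSE],
                             patience)
        members <- cand[sel$members]
        if (!length(members) || sel$merit <= 0)
            members <- cand[1L]
        pred[g, ] <- .fastFitPredict(tXtr[, members, drop = FALSE],
                                     tXtr[, g], tXev[, members, drop = FALSE],
                                     cost, tolerance, epsilon)
    }
    pred
}

#' Bootstrap residual distribution for one gene
#'
#' Repeats `nRounds` random 60/40 splits of the training samples; in each
#' round the gene's regulators are re-selected and an SVR model fitted on
#' the 60% part, and out-of-sample residuals (observed minus predicted)
#' are collected on the 40% part.  The pooled residuals are summarized by
#' their mean and standard deviation.
#'
#' @param x an [ExpressionCompendium-class]; treated samples are excluded.
#' @param gene gene identifier.
#' @param nRounds number of bootstrap rounds (default 25).
#' @param nKeep,nBins,patience feature-selection controls (see
#'   [rankAndPrefilter()] and [cfsForwardSearch()]).
#' @param trainFraction fraction of training samples in the fit split
#'   (default 0.6).
#' @param cost,tolerance,epsilon SVR hyper-parameters (see [trainSVR()]).
#' @param seed optional integer seed.
#' @return A [ResidualDistribution-class].
#' @export
bootstrapResiduals <- function(x, gene, nRounds = 25L, nKeep = 100L,
                               nBins = 10L, patience = 5L,
                               trainFraction = 0.6, cost = 0.8,
                               tolerance = 0.001, epsilon = 1e-12,
                               seed = NULL) {
    vals <- exprValues(x)
    train <- trainingSamples(x)
    if (length(train) < 5) stop("at least 5 training samples are required")
    if (!gene %in% rownames(vals)) stop("unknown gene: ", gene)
    .withSeed(seed, {
        res <- numeric(0)
        for (r in seq_len(nRounds)) {
            idx <- sample(train)
            nTr <- round(trainFraction * length(train))
            tr <- idx[seq_len(nTr)]
            te <- idx[-seq_len(nTr)]
            bins <- .discretizeRows(vals[, tr, drop = FALSE], nBins)
            cand <- rankAndPrefilter(gene, bins, nKeep)
            sub <- cfsForwardSearch(gene, cand, vals[, tr, drop = FALSE],
                                    patience)
            model <- trainSVR(t(vals[sub@members, tr, drop = FALSE]),
                              vals[gene, tr], cost = cost,
                              tolerance = tolerance, epsilon = epsilon,
                              target = gene)
            newX <- t(vals[sub@members, te, drop = FALSE])
            colnames(newX) <- sub@members
            res <- c(res, vals[gene, te] - .predictGeneModel(model, newX))
        }
        s <- sd(res)
        methods::new("ResidualDistribution", gene = gene, mean = mean(res),
                     sd = if (is.finite(s)) s else 0,
                     nResiduals = length(res), replicates = as.integer(nRounds),
                     degenerate = !is.finite(s) || s == 0)
    })
}

#' Identify perturbed genes in a treated sample
#'
#' The full network-filtering loop.  For every gene: candidate regulators
#' are selected (equal-frequency discretization, information-gain ranking,
#' CFS forward search) and an epsilon-SVR model is fitted, inside a
#' bootstrap of `nRounds` random 60/40 splits of the training samples that
#' yields the gene's out-of-sample residual distribution; a final model
#' fitted on all training samples produces the treated-sample residual,
#' whose one-sided normal p-value under the residual distribution measures
#' the gene's inconsistency with the trained regulatory model.  Genes
#' below the adaptive threshold are reported, ranked by p-value.
#'
#' The treated sample is never used for training or residual estimation.
#' The random split is drawn once per bootstrap round and shared across
#' genes (feature selection and model fitting are still repeated per gene
#' per round), which amortizes the discretization and correlation passes.
#'
#' @param x an [ExpressionCompendium-class].
#' @param treated treated sample identifier (defaults to the unique sample
#'   with the `"treated"` role).
#' @param nRounds bootstrap rounds (default 25).
#' @param nKeep candidates retained after information-gain ranking
#'   (default 100).
#' @param nBins equal-frequency bins (default 10).
#' @param alpha family error rate for the adaptive threshold (default
#'   0.05).
#' @param adjust `"bonferroni"` (threshold `alpha / nGenes`, default) or
#'   `"BH"` (Benjamini-Hochberg step-up cutoff).
#' @param patience CFS search patience (default 5).
#' @param trainFraction fraction of training samples in each fit split.
#' @param cost,tolerance,epsilon SVR hyper-parameters.
#' @param seed optional integer seed.
#' @return A [TargetReport-class]; [reportTable()] gives the full ranked
#'   per-gene table (gene, treated residual, p-value, and the fitted
#'   residual-distribution mean/sd as `res_mean`/`res_sd`) for
#'   evaluation use.
#' @export
identifyTargets <- function(x, treated = NULL, nRounds = 25L, nKeep = 100L,
                            nBins = 10L, alpha = 0.05,
                            adjust = c("bonferroni", "BH"), patience = 5L,
                            trainFraction = 0.6, cost = 0.8,
                            tolerance = 0.001, epsilon = 1e-12,
                            seed = NULL) {
    adjust <- match.arg(adjust)
    if (is.null(treated)) {
        tt <- treatedSamples(x)
        if (length(tt) != 1)
            stop("specify 'treated': the compendium has ", length(tt),
                 " treated sample(s)")
        treated <- tt
    }
    if (!treated %in% colnames(x)) stop("unknown sample: ", treated)
    vals <- exprValues(x)
    train <- setdiff(colnames(x), treated)
    train <- intersect(trainingSamples(x), train)
    if (length(train) < 5) stop("at least 5 training samples are required")
    ids <- rownames(vals)
    G <- length(ids)
    .withSeed(seed, {
        res <- vector("list", nRounds)
        for (r in seq_len(nRounds)) {
            idx <- sample(train)
            nTr <- round(trainFraction * length(train))
            tr <- idx[seq_len(nTr)]
            te <- idx[-seq_len(nTr)]
            pred <- .fitRound(vals, tr, te, nKeep, nBins, patience,
                              cost, tolerance, epsilon)
            res[[r]] <- vals[, te, drop = FALSE] - pred
        }
        resid <- do.call(cbind, res)
        m <- rowMeans(resid)
        s <- apply(resid, 1, sd)
        # treated-sample residual from a model fitted on all training data
        predTreated <- .fitRound(vals, train, treated, nKeep, nBins,
                                 patience, cost, tolerance, epsilon)[, 1]
        obs <- vals[, treated] - predTreated
        degenerate <- !is.finite(s) | s == 0
        p <- setNames(numeric(G), ids)
        for (g in seq_len(G))
            p[g] <- if (degenerate[g]) 1 else .pval(obs[g], m[g], s[g])
        threshold <- switch(adjust,
            bonferroni = adaptThreshold(G, alpha),
            BH = {
                ps <- sort(p)
                ok <- ps <= seq_len(G) / G * alpha
                if (any(ok)) ps[max(which(ok))] else 0
            })
        report <- rankTargets(p, threshold, residuals = setNames(obs, ids))
        # expose the fitted residual distributions for downstream checks
        ft <- report@fullTable
        ft$res_mean <- m[ft$gene]
        ft$res_sd <- s[ft$gene]
        report@fullTable <- ft
        report
    })
}

#' Area under the ROC curve of a p-value ranking
#'
#' Rank-based (Mann-Whitney) AUC of `-p` as the score for the positive
#' labels, with ties handled by midranks.
#'
#' @param labels logical (or 0/1) vector: `TRUE` for genes truly perturbed.
#' @param pvalues numeric vector of p-values (smaller = stronger call).
#' @return AUC in `[0, 1]`.
#' @export
rocAUC <- function(labels, pvalues) {
    labels <- as.logical(labels)
    if (length(labels) != length(pvalues))
        stop("'labels' and 'pvalues' must have equal length")
    nPos <- sum(labels)
    nNeg <- sum(!labels)
    if (nPos == 0 || nNeg == 0)
        stop("both a positive and a negative label are required")
    r <- rank(-pvalues, ties.method = "average")
    (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
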