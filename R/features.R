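# Per-gene regulator selection: equal-frequency discretization,
# information-gain ranking, and correlation-based (CFS) forward search.

#' Equal-frequency discretization
#'
#' Assigns each value to one of `nBins` bins with cut points at the
#' empirical quantiles (type-7).  Equal values always share a bin, so ties
#' are never split across a cut; with all-distinct values the bin
#' occupancies differ by at most one.  A constant vector collapses into a
#' single bin.
#'
#' @param values numeric vector (at least one value).
#' @param nBins number of bins (default 10).
#' @return Integer bin assignments in `0 .. nBins - 1`.
#' @examples
#' discretizeEqualFrequency(c(5, 1, 3, 2, 4), nBins = 5)
#' @export
discretizeEqualFrequency <- function(values, nBins = 10L) {
    if (length(values) < 1) stop("at least one value is required")
    if (nBins < 1) stop("'nBins' must be >= 1")
    if (nBins == 1L || length(unique(values)) == 1L)
        return(rep(0L, length(values)))
    cuts <- unique(.quantile7(values, seq_len(nBins - 1) / nBins))
    bins <- findInterval(values, cuts)
    # findInterval counts cut <= x, so a cut landing exactly on a tied
    # value pushes the whole tie group above the cut: ties never split.
    as.integer(bins)
}

# type-7 empirical quantiles (linear interpolation of order statistics),
# computed directly from the sorted values for speed
.quantile7 <- function(x, probs) {
    xs <- sort.int(x, method = "quick")
    n <- length(xs)
    h <- (n - 1) * probs + 1
    lo <- pmin(floor(h), n - 1)
    xs[lo] + (h - lo) * (xs[lo + 1L] - xs[lo])
}

# row-wise discretization of a genes x samples matrix
.discretizeRows <- function(m, nBins = 10L) {
    out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
    for (i in seq_len(nrow(m)))
        out[i, ] <- discretizeEqualFrequency(m[i, ], nBins)
    out
}

#' Discretize an expression matrix gene-wise
#'
#' @param x an [ExpressionCompendium-class] or a genes-by-samples matrix.
#' @param nBins number of equal-frequency bins per gene (default 10).
#' @return Integer matrix of bin assignments (genes by samples).
#' @export
discretizeMatrix <- function(x, nBins = 10L) {
    m <- if (methods::is(x, "ExpressionCompendium")) exprValues(x)
         else as.matrix(x)
    .discretizeRows(m, nBins)
}

.binEntropy <- function(bins) {
    p <- tabulate(bins + 1L)
    p <- p[p > 0] / length(bins)
    -sum(p * log2(p))
}

#' Information gain between two discretized genes
#'
#' `IG(T, a) = H(T) - sum_v |T_v|/|T| * H(T_v)` where `T_v` is the subset
#' of samples in which attribute `a` falls in bin `v`; entropies in bits.
#' Always in `[0, H(T)]` and invariant under relabeling of bin indices.
#'
#' @param targetBins,attrBins integer bin assignments of equal length
#'   (0-based, as returned by [discretizeEqualFrequency()]).
#' @return Information gain in bits.
#' @export
informationGain <- function(targetBins, attrBins) {
    if (length(targetBins) != length(attrBins))
        stop("'targetBins' and 'attrBins' must have equal length")
    if (length(targetBins) < 1) stop("at least one sample is required")
    b <- rbind(as.integer(targetBins), as.integer(attrBins))
    ig_columns_cpp(b, max(b) + 1L, 1L)[2, 1]
}

#' Information gain of every gene with respect to every target
#'
#' @param bins integer genes-by-samples bin matrix (with gene rownames).
#' @param targets target gene identifiers or row indices (default: all).
#' @return Matrix (genes by targets) of information gain in bits.
#' @export
informationGainMatrix <- function(bins, targets = seq_len(nrow(bins))) {
    if (is.character(targets)) targets <- match(targets, rownames(bins))
    out <- ig_columns_cpp(bins, max(bins) + 1L, as.integer(targets))
    dimnames(out) <- list(rownames(bins), rownames(bins)[targets])
    out
}

#' Rank genes by information gain and keep the most informative
#'
#' Ranks all other genes by their information gain with respect to the
#' target gene's bins and retains the `nKeep` most informative, ties
#' broken by gene-identifier order.  Optionally uses the gain ratio
#' (information gain divided by the attribute's split entropy) instead.
#'
#' @param target target gene identifier.
#' @param bins integer genes-by-samples bin matrix with gene rownames.
#' @param nKeep number of candidates to retain (default 100).
#' @param method `"ig"` (information gain, default) or `"gainratio"`.
#' @return Character vector of candidate gene identifiers, best first.
#' @export
rankAndPrefilter <- function(target, bins, nKeep = 100L,
                             method = c("ig", "gainratio")) {
    method <- match.arg(method)
    ids <- rownames(bins)
    ti <- match(target, ids)
    if (is.na(ti)) stop("unknown target gene: ", target)
    score <- ig_columns_cpp(bins, max(bins) + 1L, ti)[, 1]
    if (method == "gainratio") {
        splitH <- apply(bins, 1, .binEntropy)
        score <- ifelse(splitH > 0, score / splitH, 0)
    }
    score[ti] <- -Inf
    ord <- order(-score, ids)
    ids[ord][seq_len(min(nKeep, length(ids) - 1L))]
}

#' CFS merit of a feature subset
#'
#' `M_S = k * rcf / sqrt(k + k * (k - 1) * rff)`: the heuristic merit of a
#' subset of `k` features with mean feature-class correlation `rcf` and
#' mean feature-feature inter-correlation `rff`.  High merit rewards
#' subsets strongly correlated with the target but weakly correlated with
#' each other.
#'
#' @param k subset size, `>= 1`.
#' @param rcf mean feature-class correlation, in `[-1, 1]`.
#' @param rff mean feature-feature correlation, in `[-1, 1]`.
#' @return The merit score.
#' @examples
#' cfsMerit(2, 0.5, 0)   # 1/sqrt(2)
#' cfsMerit(2, 0.5, 1)   # 0.5
#' @export
cfsMerit <- function(k, rcf, rff) {
    if (k < 1) stop("'k' must be >= 1")
    if (abs(rcf) > 1 || abs(rff) > 1)
        stop("correlations must lie in [-1, 1]")
    rad <- k + k * (k - 1) * rff
    if (rad <= 0) stop("nonpositive radicand in CFS merit (rff too negative)")
    k * rcf / sqrt(rad)
}

# Greedy forward search over candidate indices given the feature-class
# correlations `rcf` and feature-feature correlation matrix `Rff`
# (absolute values).  Running sums make the merit update O(k * m):
# M = sum(rcf) / sqrt(k + 2 * sumPairs).
.cfsSearchIdx <- function(rcf, Rff, patience = 5L) {
    m <- length(rcf)
    selected <- integer(0)
    remaining <- seq_len(m)
    sumRcf <- 0
    sumPairs <- 0
    bestMerit <- -Inf
    bestK <- 0L
    fails <- 0L
    k <- 0L
    while (length(remaining) && fails < patience) {
        k1 <- k + 1L
        add <- if (k) colSums(Rff[selected, remaining, drop = FALSE])
               else numeric(length(remaining))
        merits <- (sumRcf + rcf[remaining]) / sqrt(k1 + 2 * (sumPairs + add))
        j <- which.max(merits)
        mer <- merits[j]
        pick <- remaining[j]
        selected <- c(selected, pick)
        sumRcf <- sumRcf + rcf[pick]
        sumPairs <- sumPairs + add[j]
        remaining <- remaining[-j]
        k <- k1
        if (mer > bestMerit + 1e-12) {
            bestMerit <- mer
            bestK <- k
            fails <- 0L
        } else fails <- fails + 1L
    }
    list(members = selected[seq_len(bestK)],
         merit = if (bestK) bestMerit else 0)
}

# absolute correlation matrix among rows; NAs (zero variance) -> 0
.absCor <- function(m) {
    cr <- abs(suppressWarnings(cor(t(m))))
    cr[is.na(cr)] <- 0
    cr
}

#' CFS forward subset search
#'
#' Greedy forward search maximizing the CFS merit over the candidate
#' regulators of a target gene: at each step the single feature whose
#' addition maximizes the merit is added; the search terminates when
#' `patience` consecutive expansions fail to beat the best merit seen (or
#' the candidates are exhausted) and the best subset encountered is
#' returned.  If no feature achieves positive merit the single top-ranked
#' candidate is returned as a fallback, so every gene gets a model.
#'
#' Correlations are absolute Pearson correlations of the raw expression
#' values by default; `correlation = "su"` uses symmetrical uncertainty
#' `2 IG(a,b) / (H(a) + H(b))` on the discretized values instead.
#'
#' @param target target gene identifier.
#' @param candidates candidate gene identifiers (best-first, e.g. from
#'   [rankAndPrefilter()]); nonempty.
#' @param x an [ExpressionCompendium-class] or genes-by-samples matrix of
#'   raw values (must contain target and candidates).
#' @param patience consecutive non-improving expansions tolerated
#'   (default 5).
#' @param correlation `"pearson"` (default) or `"su"`.
#' @param nBins bins used when `correlation = "su"`.
#' @return A [FeatureSubset-class].
#' @export
cfsForwardSearch <- function(target, candidates, x, patience = 5L,
                             correlation = c("pearson", "su"),
                             nBins = 10L) {
    correlation <- match.arg(correlation)
    if (!length(candidates)) stop("'candidates' must be nonempty")
    m <- if (methods::is(x, "ExpressionCompendium")) exprValues(x)
         else as.matrix(x)
    rows <- m[c(target, candidates), , drop = FALSE]
    if (correlation == "pearson") {
        cr <- .absCor(rows)
    } else {
        b <- .discretizeRows(rows, nBins)
        ig <- ig_columns_cpp(b, max(b) + 1L,
                             seq_len(nrow(b)))
        h <- apply(b, 1, .binEntropy)
        denom <- outer(h, h, "+")
        cr <- ifelse(denom > 0, 2 * ig / denom, 0)
        dimnames(cr) <- dimnames(ig) <- list(rownames(rows), rownames(rows))
    }
    rcf <- cr[candidates, target]
    Rff <- cr[candidates, candidates, drop = FALSE]
    res <- .cfsSearchIdx(rcf, Rff, patience)
    members <- candidates[res$members]
    merit <- res$merit
    if (!length(members) || merit <= 0) {
        members <- candidates[1L]
        merit <- rcf[1L]
    }
    methods::new("FeatureSubset", targetGene = target,
                 members = as.character(members), merit = as.numeric(merit))
}
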