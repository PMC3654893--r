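# Steady-state regulatory network simulator: scale-free-like template,
# subnetwork sampling, Hill-kinetics steady states, lognormal noise and
# SNR-controlled single-gene perturbations.

.netfilterCache <- new.env(parent = emptyenv())

# Evaluate `code` under `seed` without disturbing the caller's RNG stream;
# with seed = NULL the ambient stream is used (and advanced).
.withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
            get(".Random.seed", globalenv()) else NULL
        set.seed(seed)
        on.exit({
            if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
    }
    code
}

#' Built-in template regulatory network
#'
#' A directed network generated once with a fixed internal seed, used as
#' the source for [sampleSubnetwork()] when no real template edge list is
#' supplied.  Its architecture follows curated bacterial transcriptional
#' networks: a small pool of transcription-factor nodes (a few percent of
#' the genes) arranged in a shallow hierarchy, with every other gene
#' regulated by 1-3 factors drawn preferentially by out-degree — a few
#' global hub regulators therefore control large regulons, so sampled
#' subnetworks retain most regulators of the genes they contain.  A small
#' number of extra random factor-to-gene edges introduces feedback loops.
#' At the default size the template has about 1.55 edges per gene, the
#' density of the curated E. coli-scale networks used for this kind of
#' benchmark.
#'
#' @param nGenes number of genes in the template (default 2000).
#' @param tfFraction fraction of genes acting as regulators (default 3%).
#' @param activationProb probability that an edge is an activation.
#' @param feedbackFraction extra random factor-to-gene edges (possibly
#'   cycle-forming), as a fraction of `nGenes`.
#' @return A [RegulatoryNetwork-class] (kinetics not yet assigned).  The
#'   result is deterministic (internal fixed seed) and cached per size.
#' @export
defaultTemplate <- function(nGenes = 2000, tfFraction = 0.03,
                            activationProb = 0.6,
                            feedbackFraction = 0.02) {
    key <- paste(nGenes, tfFraction, activationProb, feedbackFraction,
                 sep = "|")
    if (!is.null(.netfilterCache[[key]])) return(.netfilterCache[[key]])
    net <- .withSeed(784201L, {
        ids <- sprintf("g%04d", seq_len(nGenes))
        nTF <- max(2L, round(tfFraction * nGenes))
        outdeg <- numeric(nGenes)
        reg <- integer(0)
        tgt <- integer(0)
        # shallow TF hierarchy: each factor regulated by 1-2 earlier ones
        for (i in 2:nTF) {
            k <- min(i - 1L, sample(1:2, 1L, prob = c(.7, .3)))
            r <- sample.int(i - 1L, k, prob = outdeg[seq_len(i - 1L)] + 0.2)
            reg <- c(reg, r)
            tgt <- c(tgt, rep(i, k))
            outdeg[r] <- outdeg[r] + 1
        }
        # remaining genes: 1-3 regulators from the factor pool, chosen
        # preferentially so a few global hubs carry large regulons
        for (i in (nTF + 1L):nGenes) {
            k <- min(nTF, sample.int(3L, 1L, prob = c(.55, .35, .10)))
            r <- sample.int(nTF, k, prob = outdeg[seq_len(nTF)] + 0.2)
            reg <- c(reg, r)
            tgt <- c(tgt, rep(i, k))
            outdeg[r] <- outdeg[r] + 1
        }
        # feedback: extra random factor-to-gene edges (may close cycles)
        nExtra <- round(feedbackFraction * nGenes)
        if (nExtra > 0) {
            a <- sample.int(nTF, nExtra, replace = TRUE)
            b <- sample.int(nGenes, nExtra, replace = TRUE)
            ok <- a != b
            pairKey <- paste(c(reg, a[ok]), c(tgt, b[ok]))
            keep <- !duplicated(pairKey)[length(reg) + seq_len(sum(ok))]
            reg <- c(reg, a[ok][keep])
            tgt <- c(tgt, b[ok][keep])
        }
        sgn <- ifelse(runif(length(reg)) < activationProb,
                      "activation", "repression")
        RegulatoryNetwork(data.frame(regulator = ids[reg], target = ids[tgt],
                                     sign = sgn, stringsAsFactors = FALSE),
                          nodes = ids)
    })
    .netfilterCache[[key]] <- net
    net
}

#' Sample a connected-growth subnetwork
#'
#' Grows a subnetwork of the requested size from randomly chosen seed
#' nodes: after the seed, each added node has at least one edge (in either
#' direction) to the nodes already retained.  If growth exhausts a
#' connected region before reaching the target size a fresh seed is drawn,
#' so the result may consist of several connected components (each is later
#' simulated separately).  Edges are the source edges induced on the
#' retained nodes.
#'
#' @param source a [RegulatoryNetwork-class] to sample from.
#' @param size number of genes to retain (1..number of source nodes).
#' @param seed optional integer seed.
#' @return A [RegulatoryNetwork-class] whose `metadata` records the
#'   `additionOrder` and which additions were fresh seeds (`seedNodes`).
#' @export
sampleSubnetwork <- function(source, size, seed = NULL) {
    n <- length(source@nodes)
    if (n == 0) stop("source network is empty")
    if (size < 1 || size > n)
        stop("'size' must be between 1 and the number of source nodes (",
             n, ")")
    .withSeed(seed, {
        nodes <- source@nodes
        e <- source@edges
        idx <- seq_len(n)
        names(idx) <- nodes
        nbr <- vector("list", n)
        if (nrow(e)) {
            ri <- idx[e$regulator]; ti <- idx[e$target]
            both <- split(c(ti, ri), c(ri, ti))
            nbr[as.integer(names(both))] <- lapply(both, unique)
        }
        inSet <- logical(n)
        frontier <- logical(n)
        order <- integer(size)
        isSeed <- logical(size)
        remaining <- n
        for (k in seq_len(size)) {
            cand <- which(frontier & !inSet)
            if (length(cand) == 0) {
                cand <- which(!inSet)
                isSeed[k] <- TRUE
            }
            v <- cand[sample.int(length(cand), 1L)]
            order[k] <- v
            inSet[v] <- TRUE
            frontier[nbr[[v]]] <- TRUE
        }
        keep <- nodes[sort(order)]
        sub <- e[e$regulator %in% keep & e$target %in% keep, , drop = FALSE]
        out <- RegulatoryNetwork(sub, nodes = keep)
        out@metadata <- list(additionOrder = nodes[order], seedNodes = isSeed)
        out
    })
}

#' Assign Hill-kinetic parameters
#'
#' Draws, for every regulated (non-input) gene, a maximal transcription
#' rate and basal level, and for every edge a half-saturation constant and
#' Hill coefficient, from discrete parameter sets spanning saturating vs.
#' linear and steep vs. shallow regulation regimes.
#'
#' Each edge's half-saturation constant is anchored to its regulator's
#' typical operating level (`kScale` for input genes, `basal + vmax / 2`
#' for regulated genes) and multiplied by a factor drawn from `kSet`, so
#' half-saturation falls within the regulator's dynamic range — a constant
#' far outside that range would make the edge permanently saturated or
#' silent, i.e. not a regulation behavior observed in real organisms.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param vmaxSet,hillSet discrete sets for per-gene maximal rate and
#'   per-edge Hill coefficient.
#' @param basalFracSet discrete set of basal levels as fractions of the
#'   gene's `vmax` (leaky constitutive transcription keeps every gene's
#'   dynamic range a few-fold, as in real steady-state compendia, rather
#'   than fully on/off).
#' @param kSet discrete multipliers of the regulator's operating scale for
#'   the per-edge half-saturation constant.
#' @param kScale operating scale of the input genes (expression units);
#'   also the anchor of the log-uniform input-level range used by
#'   [simulateDataset()].
#' @param seed optional integer seed.
#' @return The network with kinetics assigned.
#' @export
assignKinetics <- function(net, vmaxSet = c(5, 10, 20),
                           basalFracSet = c(0.2, 0.5),
                           kSet = c(0.25, 0.5, 1, 2), kScale = 5,
                           hillSet = c(1L, 2L, 4L), seed = NULL) {
    .withSeed(seed, {
        e <- net@edges
        regulated <- setdiff(net@nodes, inputGenes(net))
        vmax <- sample(vmaxSet, length(regulated), replace = TRUE)
        kin <- data.frame(
            gene = regulated,
            vmax = vmax,
            basal = vmax * sample(basalFracSet, length(regulated),
                                  replace = TRUE),
            stringsAsFactors = FALSE)
        opScale <- setNames(rep(kScale, length(net@nodes)), net@nodes)
        opScale[kin$gene] <- kin$basal + kin$vmax / 2
        if (nrow(e)) {
            e$K <- sample(kSet, nrow(e), replace = TRUE) *
                opScale[e$regulator]
            e$hillN <- sample(as.integer(hillSet), nrow(e), replace = TRUE)
        }
        net@edges <- e
        net@kinetics <- kin
        net@metadata$inputScale <- kScale
        methods::validObject(net)
        net
    })
}

#' Hill regulation factor
#'
#' Fractional activity contributed by one regulator at expression level `x`:
#' `x^n / (K^n + x^n)` for activation, `K^n / (K^n + x^n)` for repression.
#' Bounded in \[0, 1\], equal to 1/2 at the half-saturation point `x = K`,
#' monotone increasing (activation) or decreasing (repression) in `x`.
#'
#' @param x regulator expression level(s), `>= 0`.
#' @param K half-saturation constant, `> 0`.
#' @param n Hill coefficient, `>= 1`.
#' @param sign `"activation"` or `"repression"`.
#' @return Numeric factor(s) in \[0, 1\].
#' @examples
#' regulationFactor(2, K = 1, n = 2, sign = "activation")  # 0.8
#' @export
regulationFactor <- function(x, K, n, sign = c("activation", "repression")) {
    sign <- match.arg(sign)
    if (any(x < 0)) stop("regulator expression must be >= 0")
    if (any(K <= 0)) stop("'K' must be > 0")
    if (any(n < 1)) stop("'n' must be >= 1")
    xn <- x^n
    kn <- K^n
    if (sign == "activation") xn / (kn + xn) else kn / (kn + xn)
}

# Precompute the evaluation plan: per-component node sets, per-target
# incoming edges, topological order for acyclic components.
.networkPlan <- function(net) {
    nodes <- net@nodes
    e <- net@edges
    inputs <- inputGenes(net)
    if (length(setdiff(setdiff(nodes, inputs), net@kinetics$gene)))
        stop("kinetics must be assigned before simulation ",
             "(see assignKinetics)")
    g <- igraph::graph_from_data_frame(
        e[, c("regulator", "target")], directed = TRUE,
        vertices = data.frame(name = nodes))
    comp <- igraph::components(g, mode = "weak")
    byTarget <- split(seq_len(nrow(e)), e$target)
    kin <- net@kinetics
    vmax <- setNames(kin$vmax, kin$gene)
    basal <- setNames(kin$basal, kin$gene)
    plans <- lapply(seq_len(comp$no), function(ci) {
        cn <- nodes[comp$membership == ci]
        sg <- igraph::induced_subgraph(g, cn)
        acyclic <- igraph::is_dag(sg)
        ord <- if (acyclic)
            igraph::V(sg)$name[igraph::topo_sort(sg)] else cn
        list(nodes = cn, order = ord, acyclic = acyclic,
             regulated = setdiff(cn, inputs))
    })
    list(plans = plans, byTarget = byTarget, edges = e,
         vmax = vmax, basal = basal, inputs = inputs, nodes = nodes)
}

# transcription rate of one gene, vectorized across experiment columns
.rateOf <- function(gene, X, plan) {
    ei <- plan$byTarget[[gene]]
    f <- 1
    for (i in ei) {
        f <- f * regulationFactor(X[plan$edges$regulator[i], ],
                                  plan$edges$K[i], plan$edges$hillN[i],
                                  plan$edges$sign[i])
    }
    plan$basal[[gene]] + plan$vmax[[gene]] * f
}

# evaluate one connected component over all experiment columns of X
.evalComponent <- function(p, X, plan, BF, damping, tol, maxIter) {
    if (p$acyclic) {
        for (gene in p$order) {
            if (gene %in% plan$inputs) next
            X[gene, ] <- .rateOf(gene, X, plan) * BF[gene, ]
        }
        return(X)
    }
    reg <- p$regulated
    X[reg, ] <- (plan$basal[reg] + plan$vmax[reg] / 2) * BF[reg, ]
    for (it in seq_len(maxIter)) {
        old <- X[reg, , drop = FALSE]
        new <- old
        for (g in reg)
            new[g, ] <- .rateOf(g, X, plan) * BF[g, ]
        upd <- (1 - damping) * old + damping * new
        X[reg, ] <- upd
        delta <- max(abs(upd - old) / (abs(old) + 1e-12))
        if (delta < tol) return(X)
    }
    stop("steady-state fixed-point iteration failed to converge after ",
         maxIter, " iterations")
}

#' Steady-state expression of a parametrized network
#'
#' Each non-input gene's level is `basal + vmax * prod(regulation factors)`
#' over its incoming edges.  Acyclic components are evaluated in
#' topological order starting from the input genes; components containing
#' feedback loops are solved by a damped fixed-point iteration.  Each
#' connected component is evaluated separately and the results merged.
#'
#' @param net a kinetics-assigned [RegulatoryNetwork-class].
#' @param inputLevels named numeric vector covering exactly
#'   [inputGenes()] of `net`.
#' @param bioFactors optional named multiplicative biological-noise factors
#'   per regulated gene (default 1, i.e. noiseless kinetics).
#' @param damping,tol,maxIter fixed-point controls for cyclic components
#'   (relative tolerance; error on non-convergence).
#' @return Named numeric vector of steady-state levels over all nodes.
#' @export
computeSteadyState <- function(net, inputLevels, bioFactors = NULL,
                               damping = 0.5, tol = 1e-8, maxIter = 10000) {
    inputs <- inputGenes(net)
    if (!setequal(names(inputLevels), inputs))
        stop("'inputLevels' must cover exactly the input genes")
    plan <- .networkPlan(net)
    if (is.null(bioFactors))
        bioFactors <- setNames(rep(1, length(net@nodes)), net@nodes)
    X <- matrix(NA_real_, length(net@nodes), 1,
                dimnames = list(net@nodes, NULL))
    X[names(inputLevels), 1] <- inputLevels
    BF <- matrix(bioFactors[net@nodes], length(net@nodes), 1,
                 dimnames = list(net@nodes, NULL))
    for (p in plan$plans)
        X <- .evalComponent(p, X, plan, BF, damping, tol, maxIter)
    setNames(X[, 1], net@nodes)
}

#' Add lognormal noise
#'
#' Observed = value + eps with `eps ~ LogNormal(mu, sigma)` parametrized
#' so that `E[eps] = fraction * value`.  A lognormal deviate is positive,
#' so the noise is an additive, value-proportional intensity term (its
#' constant relative bias is absorbed into the residual location during
#' filtering) and positivity of the matrix is preserved by construction.
#' With `sigma = 0.5` the spread of the noise is about 53% of its
#' expected value, i.e. about 5% of the signal at `fraction = 0.10`.
#'
#' @param values positive numeric vector or matrix.
#' @param fraction expected noise magnitude as a fraction of the value
#'   (0 disables noise).
#' @param sigma lognormal shape parameter.
#' @return Noisy values, same shape as `values`.
#' @export
addLognormalNoise <- function(values, fraction, sigma = 0.5) {
    if (fraction == 0) return(values)
    mu <- log(fraction * values) - sigma^2 / 2
    values + rlnorm(length(values), mu, sigma)
}

# multiplicative biological-noise factor: 1 + eps, E[eps] = fraction
.bioNoiseFactors <- function(n, fraction, sigma) {
    if (fraction == 0) return(rep(1, n))
    1 + rlnorm(n, log(fraction) - sigma^2 / 2, sigma)
}

#' Simulate a steady-state expression dataset
#'
#' One column per experiment.  External conditions are modeled by drawing
#' fresh input-gene levels per experiment (log-uniform over
#' `inputRange` times the input operating scale, so experiments span the
#' responsive part of the network's dynamic range).  Biological lognormal noise perturbs each regulated gene's
#' computed rate during the kinetics evaluation; experimental lognormal
#' noise with expected magnitude `noiseFraction * value` is added to the
#' final matrix.  Each connected sub-network is simulated separately and
#' the results merged.
#'
#' @param net a kinetics-assigned [RegulatoryNetwork-class].
#' @param nExperiments number of experiments (columns), `>= 2`.
#' @param noiseFraction expected experimental noise fraction (default 0.10).
#' @param bioNoiseFraction expected biological noise fraction applied
#'   within the kinetics (default 0.05).
#' @param lognormalSigma lognormal shape for both noise layers.
#' @param inputRange range multiplier (times the mean half-saturation
#'   constant) for log-uniform input-gene levels.
#' @param seed optional integer seed.
#' @return An [ExpressionCompendium-class] with all samples in the
#'   `"training"` role.
#' @export
simulateDataset <- function(net, nExperiments = 100, noiseFraction = 0.10,
                            bioNoiseFraction = 0.05, lognormalSigma = 0.5,
                            inputRange = c(0.5, 2), seed = NULL) {
    if (nExperiments < 2) stop("'nExperiments' must be >= 2")
    if (noiseFraction < 0 || noiseFraction >= 1)
        stop("'noiseFraction' must be in [0, 1)")
    .withSeed(seed, {
        plan <- .networkPlan(net)
        inputs <- plan$inputs
        nodes <- plan$nodes
        meanK <- net@metadata$inputScale
        if (is.null(meanK)) {
            ein <- net@edges$regulator %in% inputs
            meanK <- if (any(ein)) mean(net@edges$K[ein])
                     else if (nrow(net@edges)) mean(net@edges$K) else 1
        }
        regulated <- setdiff(nodes, inputs)
        mat <- matrix(NA_real_, length(nodes), nExperiments,
                      dimnames = list(nodes,
                                      sprintf("exp_%03d", seq_len(nExperiments))))
        mat[inputs, ] <- exp(runif(length(inputs) * nExperiments,
                                   log(inputRange[1] * meanK),
                                   log(inputRange[2] * meanK)))
        BF <- matrix(1, length(nodes), nExperiments,
                     dimnames = list(nodes, NULL))
        BF[regulated, ] <- .bioNoiseFactors(length(regulated) * nExperiments,
                                            bioNoiseFraction,
                                            lognormalSigma)
        for (p in plan$plans)
            mat <- .evalComponent(p, mat, plan, BF, 0.5, 1e-8, 10000)
        mat[] <- addLognormalNoise(mat, noiseFraction, lognormalSigma)
        ExpressionCompendium(mat)
    })
}

#' Inject a single-gene perturbation
#'
#' Modifies exactly one cell of the matrix: a uniformly chosen gene (or a
#' given one) in the chosen sample has its value changed by
#' `+/- snr * noiseFraction * value`, i.e. a perturbation whose magnitude
#' is `snr` times the expected experimental noise.  The sign is a fair
#' coin, except that a subtraction that would drive the value to zero or
#' below falls back deterministically to addition (recorded in the
#' perturbation metadata).  The sample's role becomes `"treated"` and the
#' perturbed gene is recorded as simulation truth.
#'
#' @param x an [ExpressionCompendium-class].
#' @param sample sample identifier to perturb.
#' @param snr signal-to-noise ratio of the perturbation, `>= 0`.
#' @param noiseFraction the expected experimental noise fraction the SNR
#'   refers to (default 0.10).
#' @param gene optional gene identifier (default: uniform random choice).
#' @param seed optional integer seed.
#' @return The modified [ExpressionCompendium-class]; the perturbed gene is
#'   available through [perturbedTruth()] and the perturbation details
#'   through `S4Vectors::metadata(x)$perturbation`.
#' @examples
#' m <- matrix(rexp(40) + 1, 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' cpd <- injectPerturbation(ExpressionCompendium(m), "s4", snr = 16,
#'                           seed = 1)
#' perturbedTruth(cpd)
#' @export
injectPerturbation <- function(x, sample, snr, noiseFraction = 0.10,
                               gene = NULL, seed = NULL) {
    if (!sample %in% colnames(x)) stop("unknown sample: ", sample)
    if (snr < 0) stop("'snr' must be >= 0")
    .withSeed(seed, {
        if (is.null(gene))
            gene <- rownames(x)[sample.int(nrow(x), 1L)]
        v <- SummarizedExperiment::assay(x, "exprs")[gene, sample]
        delta <- snr * noiseFraction * v
        sgn <- sample(c(-1, 1), 1L)
        fallback <- FALSE
        if (sgn < 0 && v - delta <= 0) {
            sgn <- 1
            fallback <- TRUE
        }
        if (delta > 0)
            SummarizedExperiment::assay(x, "exprs")[gene, sample] <-
                v + sgn * delta
        SummarizedExperiment::colData(x)[sample, "role"] <- "treated"
        SummarizedExperiment::colData(x)[sample, "perturbedGene"] <- gene
        S4Vectors::metadata(x)$perturbation <-
            list(sample = sample, gene = gene, delta = sgn * delta,
                 signFallback = fallback)
        methods::validObject(x)
        x
    })
}
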