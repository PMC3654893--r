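# Readers/writers, run configuration and the simulation benchmark driver.

#' Read an expression matrix
#'
#' Tab-separated text: a header row of sample identifiers, one row per
#' gene with the gene identifier in the first column, raw positive
#' intensities elsewhere.  Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param treated optional character vector of sample ids to mark with the
#'   `"treated"` role; alternatively `truthPath` names a truth sidecar
#'   (tab-separated `sample_id`, `perturbed_gene_id`) whose samples are
#'   marked treated with their truth recorded.
#' @param truthPath optional path to a truth sidecar file.
#' @return An [ExpressionCompendium-class].
#' @export
readExpression <- function(path, treated = character(0), truthPath = NULL) {
    tab <- read.delim(path, header = TRUE, check.names = FALSE,
                      comment.char = "#", stringsAsFactors = FALSE,
                      fill = FALSE)
    genes <- as.character(tab[[1]])
    dup <- unique(genes[duplicated(genes)])
    if (length(dup))
        stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
    rownames(vals) <- genes
    bad <- which(vals <= 0 | !is.finite(vals), arr.ind = TRUE)
    if (nrow(bad))
        stop("nonpositive expression value at gene '",
             genes[bad[1, 1]], "', sample '", colnames(vals)[bad[1, 2]],
             "'")
    truth <- character(0)
    if (!is.null(truthPath)) {
        tt <- read.delim(truthPath, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
        truth <- setNames(as.character(tt[[2]]), as.character(tt[[1]]))
        treated <- union(treated, names(truth))
    }
    roles <- ifelse(colnames(vals) %in% treated, "treated", "training")
    ExpressionCompendium(vals, roles = roles, perturbedGene = truth)
}

#' Write an expression matrix (and truth sidecar)
#'
#' @param x an [ExpressionCompendium-class].
#' @param path output path (tab-separated).  If the compendium carries
#'   simulation truth, a sidecar `<path>.truth.tsv` with columns
#'   `sample_id`, `perturbed_gene_id` is written next to it.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
    vals <- exprValues(x)
    txt <- matrix(sprintf("%.17g", vals), nrow(vals),  # lossless round trip
                  dimnames = dimnames(vals))
    tab <- data.frame(gene = rownames(vals), txt, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- perturbedTruth(x)
    if (length(truth))
        write.table(data.frame(sample_id = names(truth),
                               perturbed_gene_id = truth),
                    paste0(path, ".truth.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a regulatory-network edge list
#'
#' Tab-separated, 3 columns (`regulator_id`, `target_id`, sign `+`/`-`);
#' `#` comment lines ignored.
#'
#' @param path file path.
#' @return A [RegulatoryNetwork-class] (kinetics not assigned).
#' @export
readEdgeList <- function(path) {
    tab <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 3) stop("edge list needs 3 columns in ", path)
    RegulatoryNetwork(data.frame(regulator = tab[[1]], target = tab[[2]],
                                 sign = tab[[3]], stringsAsFactors = FALSE))
}

#' @rdname readEdgeList
#' @param net a [RegulatoryNetwork-class].
#' @export
writeEdgeList <- function(net, path) {
    e <- networkEdges(net)
    write.table(data.frame(e$regulator, e$target,
                           ifelse(e$sign == "activation", "+", "-")),
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

.configDefaults <- function() list(
    bins = 10L, nKeep = 100L, cost = 0.8, tolerance = 0.001,
    epsilon = 1e-12, rounds = 25L, alpha = 0.05, cutoff = 0.01,
    noiseFraction = 0.10, bioNoiseFraction = 0.05, lognormalSigma = 0.5,
    snr = 4, seed = NA_integer_, patience = 5L, trainFraction = 0.6,
    genes = 200L, experiments = 100L, replicates = 30L)

#' Run configuration
#'
#' Validated bundle of all pipeline parameters with their defaults.
#' Unknown keys are rejected.
#'
#' @param ... overrides of the default fields (`bins`, `nKeep`, `cost`,
#'   `tolerance`, `epsilon`, `rounds`, `alpha`, `cutoff`, `noiseFraction`,
#'   `bioNoiseFraction`, `lognormalSigma`, `snr`, `seed`, `patience`,
#'   `trainFraction`, `genes`, `experiments`, `replicates`).
#' @return A named list of class `"netfilterConfig"` with a provenance
#'   stamp (`version`, `timestamp`).
#' @export
runConfig <- function(...) {
    defaults <- .configDefaults()
    args <- list(...)
    if (length(args) && is.null(names(args)))
        stop("configuration values must be named")
    unknown <- setdiff(names(args), names(defaults))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(defaults, args)
    stopifnot(cfg$bins >= 1, cfg$nKeep >= 1, cfg$cost > 0,
              cfg$tolerance > 0, cfg$epsilon >= 0, cfg$rounds >= 1,
              cfg$alpha > 0, cfg$alpha < 1, cfg$cutoff > 0,
              cfg$cutoff <= 1, cfg$noiseFraction >= 0,
              cfg$noiseFraction < 1, cfg$bioNoiseFraction >= 0,
              cfg$lognormalSigma > 0, cfg$snr >= 0, cfg$patience >= 1,
              cfg$trainFraction > 0, cfg$trainFraction < 1,
              cfg$genes >= 2, cfg$experiments >= 2, cfg$replicates >= 1)
    cfg$version <- as.character(utils::packageVersion("netfilter"))
    cfg$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    class(cfg) <- "netfilterConfig"
    cfg
}

#' Read a run configuration file
#'
#' Flat `key = value` text; `#` comments and blank lines ignored.  Values
#' given on the command line (or as `...` overrides here) take precedence
#' over file values.
#'
#' @param path file path.
#' @param ... overrides applied on top of the file values.
#' @return A `netfilterConfig` (see [runConfig()]).
#' @export
readRunConfig <- function(path, ...) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "\\s*=\\s*")
    bad <- lengths(kv) != 2
    if (any(bad)) stop("malformed configuration line: ", lines[bad][1])
    vals <- lapply(kv, function(p) {
        v <- utils::type.convert(p[2], as.is = TRUE)
        v
    })
    names(vals) <- vapply(kv, `[`, "", 1)
    cfg <- do.call(runConfig, vals)
    over <- list(...)
    if (length(over)) cfg <- do.call(runConfig, utils::modifyList(
        vals, over))
    cfg
}

# provenance header comment written atop every output table
.configHeader <- function(cfg = NULL) {
    if (is.null(cfg)) cfg <- runConfig()
    fields <- setdiff(names(unclass(cfg)), c("version", "timestamp"))
    paste0("# netfilter ", cfg$version, " | ", cfg$timestamp, " | ",
           paste(fields, vapply(unclass(cfg)[fields], format, ""),
                 sep = "=", collapse = " "))
}

#' Write a target report
#'
#' Tab-separated columns `rank`, `gene_id`, `residual`, `p_value` with a
#' provenance header comment; the full per-gene table is written next to
#' it as `<path minus .tsv>.full.tsv`.
#'
#' @param report a [TargetReport-class].
#' @param path output path.
#' @param config optional `netfilterConfig` recorded in the header.
#' @return `path`, invisibly.
#' @export
writeTargetReport <- function(report, path, config = NULL) {
    hdr <- .configHeader(config)
    writeReportTable <- function(tab, p) {
        con <- file(p, "w")
        on.exit(close(con))
        writeLines(hdr, con)
        write.table(data.frame(rank = tab$rank, gene_id = tab$gene,
                               residual = tab$residual,
                               p_value = tab$p_value), con, sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    writeReportTable(reportEntries(report), path)
    writeReportTable(reportTable(report),
                     paste0(sub("\\.tsv$", "", path), ".full.tsv"))
    invisible(path)
}

#' Reproduce the simulated mode-of-action benchmark
#'
#' For each signal-to-noise ratio: samples one network of `nGenes` genes
#' from the template, assigns kinetics, and simulates `nReplicates`
#' datasets of `nExperiments` steady-state experiments (99 unperturbed
#' plus 1 perturbed under the defaults) with lognormal noise; a single
#' uniformly chosen gene in the last experiment is perturbed by
#' `snr * noiseFraction * value`.  The identification pipeline is run per
#' dataset training only on the unperturbed experiments, gene-level
#' p-values are pooled across replicates, and the ROC AUC of the p-value
#' ranking against the perturbed-gene truth is computed per SNR.
#'
#' @param nGenes network size (default 200).
#' @param snr vector of signal-to-noise ratios (default `c(16, 4, 2)`).
#' @param nReplicates datasets per SNR (default 30).
#' @param nExperiments experiments per dataset (default 100: 99
#'   unperturbed + 1 perturbed).
#' @param template source network ([RegulatoryNetwork-class]); default
#'   [defaultTemplate()].
#' @param nRounds,nKeep,nBins,alpha,patience pipeline controls (see
#'   [identifyTargets()]).
#' @param noiseFraction,bioNoiseFraction,lognormalSigma simulator noise
#'   controls (see [simulateDataset()]).
#' @param seed integer seed making the whole run reproducible.
#' @param verbose print per-dataset progress.
#' @return A list with `auc` (data.frame: snr, auc, se, lower, upper,
#'   nPos, nNeg), `roc` (per-SNR ROC points), and `scores` (the pooled
#'   per-gene p-value table with truth labels).
#' @export
runBenchmark <- function(nGenes = 200, snr = c(16, 4, 2),
                         nReplicates = 30, nExperiments = 100,
                         template = NULL, nRounds = 10, nKeep = 50,
                         nBins = 10, alpha = 0.05, patience = 5,
                         noiseFraction = 0.10, bioNoiseFraction = 0.05,
                         lognormalSigma = 0.5, seed = NULL,
                         verbose = FALSE) {
    if (is.null(template))
        template <- defaultTemplate(max(2000, 2 * nGenes))
    .withSeed(seed, {
        net <- assignKinetics(sampleSubnetwork(template, nGenes))
        scores <- list()
        for (s in snr) {
            for (r in seq_len(nReplicates)) {
                dat <- simulateDataset(net, nExperiments,
                                       noiseFraction = noiseFraction,
                                       bioNoiseFraction = bioNoiseFraction,
                                       lognormalSigma = lognormalSigma)
                treated <- colnames(dat)[nExperiments]
                dat <- injectPerturbation(dat, treated, snr = s,
                                          noiseFraction = noiseFraction)
                rep <- identifyTargets(dat, treated = treated,
                                       nRounds = nRounds, nKeep = nKeep,
                                       nBins = nBins, alpha = alpha,
                                       patience = patience)
                tab <- reportTable(rep)
                tab$snr <- s
                tab$replicate <- r
                tab$label <- tab$gene == perturbedTruth(dat)[[treated]]
                scores[[length(scores) + 1L]] <- tab
                if (verbose)
                    message("snr=", s, " replicate ", r, "/", nReplicates,
                            ": perturbed gene rank ",
                            tab$rank[tab$label])
            }
        }
        scores <- do.call(rbind, scores)
        aucRows <- list()
        roc <- list()
        for (s in snr) {
            sub <- scores[scores$snr == s, ]
            a <- rocAUC(sub$label, sub$p_value)
            nPos <- sum(sub$label)
            nNeg <- sum(!sub$label)
            # Hanley-McNeil standard error of the AUC
            q1 <- a / (2 - a)
            q2 <- 2 * a^2 / (1 + a)
            se <- sqrt((a * (1 - a) + (nPos - 1) * (q1 - a^2) +
                        (nNeg - 1) * (q2 - a^2)) / (nPos * nNeg))
            aucRows[[as.character(s)]] <- data.frame(
                snr = s, auc = a, se = se,
                lower = max(0, a - 1.96 * se),
                upper = min(1, a + 1.96 * se),
                nPos = nPos, nNeg = nNeg)
            ord <- order(sub$p_value)
            roc[[as.character(s)]] <- data.frame(
                fpr = c(0, cumsum(!sub$label[ord]) / nNeg),
                tpr = c(0, cumsum(sub$label[ord]) / nPos))
        }
        list(auc = do.call(rbind, c(aucRows, list(make.row.names = FALSE))),
             roc = roc, scores = scores)
    })
}
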