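# Hypergeometric over-/under-representation of annotation terms among the
# reported genes, with conditional testing on the term hierarchy: when a
# child term is significant its genes are removed from the parents' counts
# before the parents are tested (classic conditional procedure).

#' Hypergeometric enrichment p-value
#'
#' `X ~ Hypergeometric(N, K, n)`: the number of annotated genes among `n`
#' draws from a universe of `N` genes of which `K` carry the term.
#' Over-representation tests `P(X >= k)`, under-representation `P(X <= k)`.
#'
#' @param k observed hits in the gene list.
#' @param K term size in the universe.
#' @param n gene-list size.
#' @param N universe size.
#' @param direction `"over"` (default) or `"under"`.
#' @return p-value in `(0, 1]`.
#' @examples
#' hypergeomPvalue(2, 3, 5, 10)  # 0.5
#' @export
hypergeomPvalue <- function(k, K, n, N, direction = c("over", "under")) {
    direction <- match.arg(direction)
    if (k < 0 || K < 0 || n < 0 || N < 0 || K > N || n > N ||
        k > min(n, K))
        stop("inconsistent counts: need 0 <= k <= min(n, K), K <= N, n <= N")
    if (direction == "over")
        phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    else
        phyper(k, K, N - K, n)
}

# normalize annotations to a term -> genes list
.termGenes <- function(annotations) {
    if (is.data.frame(annotations)) {
        ann <- annotations
        colnames(ann)[1:2] <- c("gene", "term")
    } else if (is.list(annotations)) {
        ann <- data.frame(
            gene = rep(names(annotations), lengths(annotations)),
            term = unlist(annotations, use.names = FALSE),
            stringsAsFactors = FALSE)
    } else stop("'annotations' must be a data.frame or a named list")
    ann <- unique(ann[, c("gene", "term")])
    split(ann$gene, ann$term)
}

# ancestors (direct and transitive parents) per term from a child->parent
# edge table; errors on cyclic graphs
.termAncestry <- function(graph) {
    g <- igraph::graph_from_data_frame(graph[, 1:2], directed = TRUE)
    if (!igraph::is_dag(g)) stop("the term graph must be acyclic")
    order <- igraph::V(g)$name[igraph::topo_sort(g, mode = "out")]
    parents <- split(graph[[2]], graph[[1]])
    anc <- list()
    for (t in rev(order)) {  # roots first, so parents' ancestors exist
        pa <- unique(parents[[t]])
        anc[[t]] <- unique(c(pa, unlist(anc[pa], use.names = FALSE)))
    }
    list(order = order, parents = parents, ancestors = anc)
}

#' Conditional term enrichment of a gene list
#'
#' Hypergeometric over- or under-representation of every annotation term
#' among the reported genes.  When a term hierarchy is supplied,
#' annotations are first propagated to ancestor terms, terms are tested
#' leaves-upward, and whenever a child term is significant at `cutoff` its
#' genes are removed from its parents' counts before the parents are
#' tested, so parents significant only through a significant child drop
#' out.  Without a hierarchy the procedure reduces to independent
#' hypergeometric tests.
#'
#' @param genes character vector of reported genes (entries outside the
#'   universe are dropped with a warning).
#' @param annotations gene-to-term map: a data.frame with columns
#'   `gene`, `term`, or a named list mapping gene to term ids.
#' @param graph optional term hierarchy: data.frame with columns
#'   `child`, `parent` (must be acyclic).
#' @param cutoff significance cutoff (default 0.01).
#' @param direction `"over"` (default) or `"under"`.
#' @param universe universe of genes; defaults to all annotated genes.
#' @param propagate propagate annotations to ancestor terms before testing
#'   (default `TRUE`; ignored without a graph).
#' @return data.frame of significant terms (`term`, `p_value`, `k`, `n`,
#'   `K`, `N`, `direction`) sorted by p-value; the full table over all
#'   terms is attached as `attr(, "fullResults")`.
#' @export
conditionalEnrichment <- function(genes, annotations, graph = NULL,
                                  cutoff = 0.01,
                                  direction = c("over", "under"),
                                  universe = NULL, propagate = TRUE) {
    direction <- match.arg(direction)
    tg <- .termGenes(annotations)
    ancestry <- if (!is.null(graph) && nrow(graph)) .termAncestry(graph)
                else NULL
    if (!is.null(ancestry) && propagate) {
        for (t in ancestry$order) {
            for (pa in ancestry$parents[[t]])
                tg[[pa]] <- unique(c(tg[[pa]], tg[[t]]))
        }
    }
    if (is.null(universe))
        universe <- unique(unlist(tg, use.names = FALSE))
    tg <- lapply(tg, intersect, universe)
    genes <- unique(genes)
    outside <- setdiff(genes, universe)
    if (length(outside)) {
        warning(length(outside), " gene(s) outside the annotated universe ",
                "dropped")
        genes <- intersect(genes, universe)
    }
    N <- length(universe)
    n <- length(genes)
    terms <- names(tg)
    # leaves-upward order: children before parents
    if (!is.null(ancestry))
        terms <- c(intersect(ancestry$order, terms),
                   setdiff(terms, ancestry$order))
    removed <- setNames(vector("list", length(terms)), terms)
    rows <- vector("list", length(terms))
    for (i in seq_along(terms)) {
        t <- terms[i]
        eff <- setdiff(tg[[t]], removed[[t]])
        K <- length(eff)
        if (K == 0) next
        k <- length(intersect(eff, genes))
        p <- hypergeomPvalue(k, K, n, N, direction)
        rows[[i]] <- data.frame(term = t, p_value = p, k = k, n = n,
                                K = K, N = N, direction = direction,
                                stringsAsFactors = FALSE)
        if (p <= cutoff && !is.null(ancestry)) {
            for (pa in ancestry$parents[[t]]) {
                if (pa %in% names(removed))
                    removed[[pa]] <- unique(c(removed[[pa]], tg[[t]]))
            }
        }
    }
    full <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(full))
        full <- data.frame(term = character(0), p_value = numeric(0),
                           k = integer(0), n = integer(0), K = integer(0),
                           N = integer(0), direction = character(0))
    full <- full[order(full$p_value, full$term), , drop = FALSE]
    rownames(full) <- NULL
    sig <- full[full$p_value <= cutoff, , drop = FALSE]
    rownames(sig) <- NULL
    attr(sig, "fullResults") <- full
    sig
}

#' Read a gene-to-term annotation table
#'
#' Accepts a 2-column tab-separated table (`gene_id`, `term_id`) or a
#' GAF 2.x file (lines starting with `!` are headers; the object symbol,
#' column 3, and the term id, column 5, are used).
#'
#' @param path file path.
#' @return data.frame with columns `gene`, `term`.
#' @export
readAnnotations <- function(path) {
    first <- readLines(path, n = 1L)
    if (startsWith(first, "!")) {
        tab <- read.delim(path, header = FALSE, comment.char = "!",
                          stringsAsFactors = FALSE)
        data.frame(gene = tab[[3]], term = tab[[5]],
                   stringsAsFactors = FALSE)
    } else {
        tab <- read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
        data.frame(gene = tab[[1]], term = tab[[2]],
                   stringsAsFactors = FALSE)
    }
}

#' Read a term hierarchy
#'
#' Accepts a 2-column tab-separated table (`child`, `parent`) or an
#' OBO-format file, of which only `id:` and `is_a:` relations are used.
#'
#' @param path file path.
#' @return data.frame with columns `child`, `parent`.
#' @export
readTermGraph <- function(path) {
    lines <- readLines(path)
    if (any(grepl("^\\[Term\\]", lines))) {
        child <- character(0)
        parent <- character(0)
        cur <- NA_character_
        for (ln in lines) {
            if (grepl("^\\[", ln)) cur <- NA_character_
            if (startsWith(ln, "id: ")) cur <- sub("^id: *", "", ln)
            if (startsWith(ln, "is_a:") && !is.na(cur)) {
                pa <- sub("^is_a: *([^ !]+).*$", "\\1", ln)
                child <- c(child, cur)
                parent <- c(parent, pa)
            }
        }
        data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
    } else {
        tab <- read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
        data.frame(child = tab[[1]], parent = tab[[2]],
                   stringsAsFactors = FALSE)
    }
}
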