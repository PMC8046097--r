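#' Pathway over-representation analysis
#'
#' One-sided hypergeometric (Fisher) over-representation test: for each
#' pathway the p-value is the probability of at least the observed number of
#' query hits when drawing `|query|` metabolites from the background.
#' Pathway membership is first intersected with the background (the measured,
#' filter-surviving metabolites mappable to any pathway, by default supplied
#' by the caller); pathways with no mappable member are skipped.  P-values
#' are BH-adjusted across tested pathways and rows are sorted by p.
#'
#' @param query metabolite id set (must be a subset of `background`).
#' @param background metabolite id universe.
#' @param pathways named list as from [readPathwayGMT()].
#' @param graphs optional named list of edge data.frames (per pathway) for
#'   the topology impact column.
#' @return a `data.frame`: `id`, `name`, `total` (pathway members in the
#'   background), `hits`, `hitIds` (comma-joined), `p`, `padj`, `impact`
#'   (`NA` without a graph).
#' @examples
#' pw <- list(P1 = list(name = "demo", members = paste0("M", 1:10)))
#' enrich(paste0("M", 1:5), paste0("M", 1:100), pw)
#' @export
enrich <- function(query, background, pathways, graphs = NULL) {
    query <- unique(query); background <- unique(background)
    .stopIfNot(length(query) > 0, "empty query set")
    extra <- setdiff(query, background)
    .stopIfNot(length(extra) == 0, "query not contained in background: %s",
               paste(head(extra, 5), collapse = ", "))
    N <- length(background); n <- length(query)
    rows <- lapply(names(pathways), function(pid) {
        members <- intersect(pathways[[pid]]$members, background)
        if (length(members) == 0L) {
            message("pathway ", pid, " has no mappable member; skipped")
            return(NULL)
        }
        hits <- intersect(query, members)
        K <- length(members); k <- length(hits)
        p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        imp <- if (!is.null(graphs[[pid]]))
            pathwayImpact(graphs[[pid]], hits) else NA_real_
        data.frame(id = pid, name = pathways[[pid]]$name, total = K,
                   hits = k, hitIds = paste(sort(hits), collapse = ","),
                   p = p, impact = imp, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    .stopIfNot(!is.null(out), "no pathway overlaps the background")
    out$padj <- adjustP(out$p)
    out <- out[order(out$p, out$id), c("id", "name", "total", "hits",
                                       "hitIds", "p", "padj", "impact")]
    rownames(out) <- NULL
    out
}

#' Topology-based pathway impact
#'
#' The impact of a hit set on a pathway reaction graph is the share of total
#' relative betweenness centrality carried by the hit nodes:
#' `sum(betweenness of hits) / sum(betweenness of all nodes)`, in \[0, 1\].
#' When every node has zero betweenness (e.g. an edgeless graph) the hit
#' fraction of nodes is returned instead, so a full hit set still scores 1.
#'
#' @param graph an [igraph::graph] or a two-column edge `data.frame`
#'   (`from`, `to`).
#' @param hitIds metabolite ids hit by the query.
#' @return impact in \[0, 1\]; 0 with a warning for an empty graph.
#' @export
pathwayImpact <- function(graph, hitIds) {
    if (is.data.frame(graph))
        graph <- igraph::graph_from_data_frame(graph, directed = FALSE)
    nodes <- igraph::V(graph)$name
    if (length(nodes) == 0L) {
        warning("empty pathway graph; impact = 0")
        return(0)
    }
    btw <- igraph::betweenness(graph, directed = FALSE)
    hit <- nodes %in% hitIds
    if (sum(btw) == 0) return(mean(hit))
    sum(btw[hit]) / sum(btw)
}
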