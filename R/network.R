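#' Build the local-motion correlation network from an MI matrix
#'
#' Nodes are fragment positions; an undirected edge joins positions `i < j`
#' when `nmi(i, j) > threshold`, the BH q-value is at most `qMax`, and (when
#' `skipOverlap` is on) the windows do not share residues (`|i - j| >= 4`).
#' Isolated nodes are retained, so the node set is always the full set of
#' positions.  Eigenvector centrality is computed on construction when the
#' network has edges.
#'
#' @param m An [MIMatrix].
#' @param threshold nMI cutoff in `[0, 1)` (default 0: significance, not
#'   magnitude, is the primary filter).
#' @param qMax FDR cutoff (default 0.05).
#' @param skipOverlap Exclude trivially-correlated overlapping-window pairs
#'   (default `TRUE`).
#' @return An [MINetwork].
#' @export
buildNetwork <- function(m, threshold = 0, qMax = 0.05, skipOverlap = TRUE) {
    stopifnot(is(m, "MIMatrix"))
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        threshold < 0 || threshold >= 1)
        .stopInput("'threshold' must lie in [0, 1)")
    p <- ncol(m@nmi)
    pairs <- which(upper.tri(m@nmi), arr.ind = TRUE)
    keep <- m@nmi[pairs] > threshold & m@qvalue[pairs] <= qMax
    if (skipOverlap) keep <- keep & !m@overlap[pairs]
    edges <- data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L],
                        weight = m@nmi[pairs][keep],
                        qvalue = m@qvalue[pairs][keep])
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
    net <- new("MINetwork",
               nodes = data.frame(id = seq_len(p), label = m@positionLabels),
               edges = edges, threshold = threshold, qMax = qMax,
               skipOverlap = skipOverlap, centrality = numeric())
    net@centrality <- if (nrow(edges)) eigenvectorCentrality(net)
                      else structure(numeric(p), names = as.character(seq_len(p)))
    net
}

setMethod("show", "MINetwork", function(object) {
    cat(sprintf("MINetwork: %d nodes, %d edges (nMI > %g, q <= %g%s)\n",
                nrow(object@nodes), nrow(object@edges), object@threshold,
                object@qMax,
                if (object@skipOverlap) ", overlapping windows excluded" else ""))
})

#' @describeIn buildNetwork Edge table (`from`, `to`, `weight`, `qvalue`).
#' @param network An `MINetwork`.
#' @export
networkEdges <- function(network) network@edges

#' @describeIn buildNetwork Node table (`id`, `label`).
#' @export
networkNodes <- function(network) network@nodes

.networkGraph <- function(network, weightTransform = identity) {
    g <- igraph::graph_from_data_frame(
        network@edges[, c("from", "to"), drop = FALSE], directed = FALSE,
        vertices = data.frame(name = as.character(network@nodes$id),
                              label = network@nodes$label))
    igraph::E(g)$weight <- weightTransform(network@edges$weight)
    g
}

#' Eigenvector centrality of the correlation network
#'
#' Scores each fragment position by the dominant eigenvector of the
#' weighted adjacency matrix of the network's largest connected component
#' (by Perron-Frobenius the dominant eigenvector of a connected non-negative
#' adjacency is non-negative).  High-centrality fragments show correlated
#' motions preferentially with other highly correlated fragments -- the key
#' positions of the coupling network.  Computed by direct symmetric eigen
#' decomposition; nodes outside the largest component score 0; the full
#' score vector is normalized to unit Euclidean norm.
#'
#' @param network An [MINetwork] with at least one edge.
#' @return Named numeric vector of non-negative scores, one per node
#'   (names are node ids), with unit Euclidean norm.
#' @export
eigenvectorCentrality <- function(network) {
    stopifnot(is(network, "MINetwork"))
    if (!nrow(network@edges))
        stop("cannot compute centrality of an edgeless network", call. = FALSE)
    ids <- network@nodes$id
    g <- .networkGraph(network)
    comp <- igraph::components(g)
    sizes <- tapply(rep(1L, length(comp$membership)), comp$membership, sum)
    largest <- as.integer(names(sizes)[which.max(sizes)])  # ties: lowest id
    inComp <- comp$membership == largest
    sub <- as.integer(igraph::V(g)$name[inComp])
    A <- matrix(0, length(sub), length(sub))
    e <- network@edges
    fi <- match(e$from, sub)
    ti <- match(e$to, sub)
    onComp <- !is.na(fi) & !is.na(ti)
    A[cbind(fi[onComp], ti[onComp])] <- e$weight[onComp]
    A[cbind(ti[onComp], fi[onComp])] <- e$weight[onComp]
    dec <- eigen(A, symmetric = TRUE)
    v <- dec$vectors[, 1L]
    if (sum(v) < 0) v <- -v
    v[v < 0] <- 0                         # numerical noise on a PF eigenvector
    scores <- structure(numeric(length(ids)), names = as.character(ids))
    scores[as.character(sub)] <- v
    scores / sqrt(sum(scores^2))
}

#' Extract ranked communication pathways between two site sets
#'
#' Finds the `k` lowest-cost loopless paths between a source node set (e.g.
#' the allosteric site) and a target set (e.g. the orthosteric site), where
#' each edge costs `-log(nMI)`: chains of strongly coupled fragments become
#' cheap additive paths, so high-correlation communication routes rank
#' first.  Ties are broken by the lexicographically smaller node sequence.
#'
#' @param network An [MINetwork].
#' @param source,target Vectors of node ids (fragment positions).
#' @param k Maximum number of paths to return (default 3).
#' @return Data frame with `rank`, `cost` (sum of `-log(nMI)`), and `path`
#'   (comma-separated node ids).  Empty (with a warning) when no route
#'   exists.
#' @export
communicationPathways <- function(network, source, target, k = 3L) {
    stopifnot(is(network, "MINetwork"))
    ids <- network@nodes$id
    bad <- setdiff(c(source, target), ids)
    if (length(bad))
        .stopInput("unknown node id(s): %s", paste(bad, collapse = ", "))
    empty <- data.frame(rank = integer(), cost = numeric(), path = character())
    if (!nrow(network@edges)) {
        warning("network has no edges; no communication pathways")
        return(empty)
    }
    g <- .networkGraph(network, weightTransform = function(w) -log(w))
    found <- list()
    for (s in source) for (t in setdiff(target, s)) {
        res <- tryCatch(
            suppressWarnings(  # igraph warns on unreachable targets; we report that ourselves
                igraph::k_shortest_paths(g, from = as.character(s),
                                         to = as.character(t), k = k)),
            error = function(e) NULL)
        if (is.null(res)) next
        for (vp in res$vpaths) {
            nodes <- as.integer(names(vp))
            ep <- igraph::E(g, path = vp)
            found[[length(found) + 1L]] <- list(
                path = paste(nodes, collapse = ","),
                cost = sum(igraph::E(g)$weight[as.integer(ep)]))
        }
    }
    if (!length(found)) {
        warning("no path connects the source and target sets")
        return(empty)
    }
    paths <- vapply(found, `[[`, character(1L), "path")
    costs <- vapply(found, `[[`, numeric(1L), "cost")
    dup <- duplicated(paths)
    paths <- paths[!dup]
    costs <- costs[!dup]
    o <- order(costs, paths)
    n <- min(length(o), k)
    data.frame(rank = seq_len(n), cost = costs[o][seq_len(n)],
               path = paths[o][seq_len(n)])
}

#' Write a correlation network as GML
#'
#' Standard GML (as consumed by Cytoscape and igraph): each node carries
#' `id` (fragment position), `label` (residue range) and `centrality`; each
#' edge carries `source`, `target` and `weight` (nMI).
#'
#' @param network An [MINetwork].
#' @param path Output path.
#' @export
writeGML <- function(network, path) {
    stopifnot(is(network, "MINetwork"))
    validObject(network)
    g <- .networkGraph(network)
    igraph::V(g)$id <- network@nodes$id
    igraph::V(g)$centrality <- if (length(network@centrality))
        unname(network@centrality) else rep(0, nrow(network@nodes))
    g <- igraph::delete_vertex_attr(g, "name")
    tmp <- paste0(path, ".partial")
    igraph::write_graph(g, tmp, format = "gml")
    # igraph stamps the Creator line with the wall clock; replace it so
    # identical networks serialize to identical bytes
    lines <- readLines(tmp)
    lines[1L] <- sprintf("Creator \"SAMotions %s\"",
                         as.character(utils::packageVersion("SAMotions")))
    writeLines(lines, tmp)
    if (!file.rename(tmp, path))
        stop(sprintf("cannot write '%s'", path), call. = FALSE)
    invisible(path)
}

#' Read a GML network file
#'
#' Re-imports a GML file written by [writeGML()] as an igraph graph, for
#' round-trip checks and downstream graph analysis.
#'
#' @param path GML file path.
#' @return An igraph graph.
#' @export
readGML <- function(path) {
    if (!file.exists(path)) .stopInput("GML file '%s' does not exist", path)
    igraph::read_graph(path, format = "gml")
}
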