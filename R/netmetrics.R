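.netIgraph <- function(net, directed = TRUE) {
  if (is(net, "CausalNetwork")) {
    edges <- networkEdges(net)
    verts <- networkNodes(net)$gene
  } else {
    edges <- .asEdgeDf(net)
    verts <- unique(c(edges$source, edges$target))
  }
  igraph::graph_from_data_frame(
    edges[, c("source", "target"), drop = FALSE],
    directed = directed, vertices = verts)
}

#' Node degree
#'
#' The number of edges incident on each node (in-degree plus
#' out-degree). Parallel opposite-direction edges are counted
#' separately; a self-loop counts once.
#'
#' @param net a \linkS4class{CausalNetwork} or an edge data.frame
#' @param node optional gene ID(s); default reports all nodes. An
#'   unknown node is an error.
#' @return named integer vector of degrees
#' @export
nodeDegree <- function(net, node = NULL) {
  g <- .netIgraph(net)
  deg <- igraph::degree(g, mode = "all", loops = FALSE)
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    loops <- el[, 1L] == el[, 2L]
    if (any(loops)) {
      tab <- table(el[loops, 1L])
      deg[names(tab)] <- deg[names(tab)] + as.integer(tab)
    }
  }
  deg <- setNames(as.integer(deg), names(deg))
  if (!is.null(node)) {
    unknown <- setdiff(node, names(deg))
    if (length(unknown))
      stop("unknown node(s): ", paste(unknown, collapse = ", "))
    deg <- deg[node]
  }
  deg
}

#' Betweenness centrality
#'
#' For each node v, the sum over ordered pairs (s, t) with s != v != t of
#' the fraction of shortest s-to-t paths passing through v, normalised by
#' (n-1)(n-2) for directed graphs (and half that for undirected), so
#' values lie in [0, 1]. Pairs with no connecting path contribute 0.
#' Self-loops are ignored.
#'
#' @param net a \linkS4class{CausalNetwork} or an edge data.frame
#' @param directed treat edges as directed (default TRUE; regulatory
#'   links have a direction)
#' @return named numeric vector of normalised betweenness values
#' @export
nodeBetweenness <- function(net, directed = TRUE) {
  g <- .netIgraph(net, directed = directed)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::vcount(g) <= 2L)  # no pairs to mediate; normaliser degenerate
    return(setNames(rep(0, igraph::vcount(g)), igraph::V(g)$name))
  igraph::betweenness(g, directed = directed, normalized = TRUE)
}

#' Degree and betweenness report for a network
#'
#' @param net a \linkS4class{CausalNetwork} or an edge data.frame
#' @param directed passed to [nodeBetweenness()]
#' @return data.frame (gene, degree, betweenness) sorted by degree
#'   descending; attributes \code{nNodes} and \code{nEdges} hold the
#'   network totals
#' @export
centralityReport <- function(net, directed = TRUE) {
  deg <- nodeDegree(net)
  btw <- nodeBetweenness(net, directed = directed)
  out <- data.frame(gene = names(deg), degree = unname(deg),
                    betweenness = unname(btw[names(deg)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  edges <- if (is(net, "CausalNetwork")) networkEdges(net) else .asEdgeDf(net)
  attr(out, "nNodes") <- nrow(out)
  attr(out, "nEdges") <- nrow(edges)
  out
}
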