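## Core causal-network construction: path restriction, iterative sign
## propagation from observed misregulated genes up to a perturbed root
## regulator, consistency pruning and shortest-path network assembly.

.asEdgeDf <- function(x) {
  if (is(x, "RegulatoryLinks")) return(interactions(x))
  stopifnot(is.data.frame(x),
            all(c("source", "sign", "target") %in% names(x)))
  if (is.null(x$evidence)) x$evidence <- ""
  x
}

.edgeGraph <- function(edges, nodes = NULL) {
  verts <- unique(c(nodes, edges$source, edges$target))
  igraph::graph_from_data_frame(
    edges[, c("source", "target"), drop = FALSE],
    directed = TRUE, vertices = verts)
}

.observedVector <- function(observed) {
  if (is.data.frame(observed)) {
    stopifnot(all(c("gene", "direction") %in% names(observed)))
    setNames(as.integer(observed$direction), observed$gene)
  } else {
    stopifnot(!is.null(names(observed)))
    setNames(as.integer(observed), names(observed))
  }
}

#' Restrict a regulatory graph to root-to-target paths
#'
#' Keeps exactly the nodes and edges lying on at least one directed path
#' from any root regulator to any target gene: the intersection of the
#' roots' descendants and the targets' ancestors (roots and targets
#' included). Targets absent from the graph or unreachable from every
#' root are returned as excluded.
#'
#' @param x a \linkS4class{RegulatoryLinks} object or an edge data.frame
#'   with columns source, sign, target (optional evidence)
#' @param roots character vector of root regulator gene IDs (non-empty)
#' @param targets character vector of target (misregulated) gene IDs
#'   (non-empty)
#' @return list with \code{edges}: the on-path edge data.frame,
#'   \code{nodes}: the on-path gene IDs, and \code{excluded}: data.frame
#'   (gene, reason = "no_path") of targets that could not be connected
#' @export
restrictToPaths <- function(x, roots, targets) {
  edges <- .asEdgeDf(x)
  stopifnot(length(roots) > 0L, length(targets) > 0L)
  g <- .edgeGraph(edges, nodes = c(roots, targets))
  verts <- igraph::V(g)$name
  fromRoots <- unique(unlist(lapply(
    intersect(roots, verts),
    function(r) verts[igraph::subcomponent(g, r, mode = "out")])))
  toTargets <- unique(unlist(lapply(
    intersect(targets, verts),
    function(t) verts[igraph::subcomponent(g, t, mode = "in")])))
  onPath <- intersect(fromRoots, toTargets)
  keep <- edges$source %in% onPath & edges$target %in% onPath
  excludedGenes <- setdiff(targets, onPath)
  if (length(excludedGenes) == length(unique(targets)))
    stop("no target is reachable from any root; excluded targets: ",
         paste(excludedGenes, collapse = ", "))
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(edges = out,
       nodes = unique(c(intersect(roots, onPath), onPath)),
       excluded = data.frame(gene = excludedGenes,
                             reason = rep("no_path", length(excludedGenes)),
                             stringsAsFactors = FALSE))
}

#' Propagate misregulation signs upstream from observed genes
#'
#' Starting from the observed misregulated genes, assigns every other
#' gene on the root-to-target paths a score equal to the sum, over its
#' signed outgoing links \code{u -> v} whose downstream gene \code{v} has
#' a known (observed or currently predicted) direction, of
#' \code{sign(link) * direction(v)}. The predicted direction is the sign
#' of the score; a zero score means no prediction can be made. Updates
#' are synchronous sweeps repeated until a fixed point (or
#' \code{maxIter}); genes still changing at the cap are marked
#' \code{no_prediction} with a warning. Observed directions and the root
#' direction are immutable. Unsigned links (sign 0) contribute nothing.
#'
#' The root direction is fixed by the perturbation: \code{knockout} means
#' the root regulator is absent (direction -1), so a repressive link from
#' the root predicts derepression (up) of its target;
#' \code{overexpression} fixes the root at +1.
#'
#' @param subgraph result of [restrictToPaths()], or an edge data.frame
#' @param observed misregulation data.frame (gene, direction) or a named
#'   vector of +1/-1 directions
#' @param roots character vector of root regulator IDs
#' @param rootMode "knockout" (root direction -1) or "overexpression" (+1)
#' @param maxIter maximum number of synchronous sweeps (default 100)
#' @return data.frame (gene, direction, score, status) — the node states;
#'   direction is NA for status \code{no_prediction}
#' @export
propagateScores <- function(subgraph, observed, roots,
                            rootMode = c("knockout", "overexpression"),
                            maxIter = 100L) {
  rootMode <- match.arg(rootMode)
  rootDir <- if (rootMode == "knockout") -1L else 1L
  edges <- if (is.list(subgraph) && !is.data.frame(subgraph))
    subgraph$edges else .asEdgeDf(subgraph)
  nodes <- if (is.list(subgraph) && !is.data.frame(subgraph))
    subgraph$nodes else unique(c(edges$source, edges$target))
  obs <- .observedVector(observed)
  stopifnot(all(obs %in% c(-1L, 1L)))
  obs <- obs[names(obs) %in% nodes]
  nodes <- unique(c(roots, nodes))

  conflictRoots <- intersect(roots, names(obs))
  if (length(conflictRoots) &&
      any(obs[conflictRoots] != rootDir))
    warning("observed direction conflicts with root mode for: ",
            paste(conflictRoots[obs[conflictRoots] != rootDir],
                  collapse = ", "), " (root mode wins)")
  obs <- obs[setdiff(names(obs), roots)]

  dir <- setNames(rep(NA_integer_, length(nodes)), nodes)
  dir[names(obs)] <- obs
  dir[intersect(roots, nodes)] <- rootDir
  fixed <- names(dir) %in% c(names(obs), roots)
  free <- nodes[!fixed]

  signed <- edges[edges$sign != 0L & edges$source %in% free, , drop = FALSE]
  score <- setNames(rep(0L, length(nodes)), nodes)
  oscillating <- character()
  if (length(free) && nrow(signed)) {
    srcIdx <- match(signed$source, nodes)
    tgtIdx <- match(signed$target, nodes)
    prev <- dir
    converged <- FALSE
    for (iter in seq_len(maxIter)) {
      contrib <- signed$sign * prev[tgtIdx]
      contrib[is.na(contrib)] <- 0L
      s <- rowsum(contrib, group = srcIdx)
      newScore <- setNames(rep(0L, length(nodes)), nodes)
      newScore[as.integer(rownames(s))] <- as.integer(s)
      newDir <- prev
      newDir[free] <- ifelse(newScore[free] == 0L, NA_integer_,
                             as.integer(sign(newScore[free])))
      score <- newScore
      if (identical(newDir, prev)) { converged <- TRUE; break }
      prev <- newDir
    }
    dir <- prev
    if (!converged) {
      # one more probe sweep identifies the genes still flipping
      contrib <- signed$sign * dir[tgtIdx]
      contrib[is.na(contrib)] <- 0L
      s <- rowsum(contrib, group = srcIdx)
      probe <- setNames(rep(0L, length(nodes)), nodes)
      probe[as.integer(rownames(s))] <- as.integer(s)
      probeDir <- ifelse(probe[free] == 0L, NA_integer_,
                         as.integer(sign(probe[free])))
      unstable <- free[!(is.na(probeDir) & is.na(dir[free])) &
                         (is.na(probeDir) | is.na(dir[free]) |
                            probeDir != dir[free])]
      if (length(unstable)) {
        warning("propagation did not converge within ", maxIter,
                " sweeps; ", length(unstable),
                " oscillating gene(s) marked no_prediction")
        dir[unstable] <- NA_integer_
        score[unstable] <- 0L
        oscillating <- unstable
      }
    }
  }
  status <- ifelse(nodes %in% roots, "root",
            ifelse(nodes %in% names(obs), "observed",
            ifelse(is.na(dir[nodes]) | nodes %in% oscillating,
                   "no_prediction", "predicted")))
  score[nodes %in% oscillating] <- 0L
  data.frame(gene = nodes, direction = unname(dir[nodes]),
             score = unname(score[nodes]), status = status,
             stringsAsFactors = FALSE)
}

#' Remove sign-inconsistent links
#'
#' A link \code{u -> v} with sign s is consistent when s is non-zero,
#' both endpoint directions are assigned (observed, predicted or root)
#' and \code{direction(u) * s == direction(v)}: an activating link
#' requires equal directions, a repressive link opposite directions.
#' Everything else — unsigned links, links touching a no-prediction gene,
#' sign contradictions — is removed.
#'
#' @param subgraph result of [restrictToPaths()] or an edge data.frame
#' @param states node-state data.frame from [propagateScores()]
#' @return list with \code{edges}: the consistent edge data.frame and
#'   \code{removed}: number of edges removed
#' @export
pruneInconsistent <- function(subgraph, states) {
  edges <- if (is.list(subgraph) && !is.data.frame(subgraph))
    subgraph$edges else .asEdgeDf(subgraph)
  dir <- setNames(states$direction, states$gene)
  du <- dir[edges$source]
  dv <- dir[edges$target]
  keep <- edges$sign != 0L & !is.na(du) & !is.na(dv) &
    du * edges$sign == dv
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(edges = out, removed = sum(!keep))
}

#' Assemble the shortest-path causal network
#'
#' The final explanatory network is the union, over every target still
#' reachable in the consistent edge set, of ALL minimum-length directed
#' root-to-target paths (ties are all kept; with several roots, each
#' root's shortest paths to the target are unioned). Targets rendered
#' unreachable by consistency pruning are recorded as excluded with
#' reason \code{"inconsistent"}.
#'
#' @param consistent consistent edge data.frame (or the list returned by
#'   [pruneInconsistent()])
#' @param states node states from [propagateScores()]
#' @param roots root regulator IDs
#' @param targets target gene IDs
#' @param priorExcluded optional data.frame (gene, reason) of targets
#'   already excluded upstream (carried through to the result)
#' @return a \linkS4class{CausalNetwork}
#' @export
shortestPathNetwork <- function(consistent, states, roots, targets,
                                priorExcluded = NULL) {
  edges <- if (is.list(consistent) && !is.data.frame(consistent))
    consistent$edges else .asEdgeDf(consistent)
  targets <- setdiff(unique(targets),
                     if (is.null(priorExcluded)) character()
                     else priorExcluded$gene)
  g <- .edgeGraph(edges, nodes = unique(c(roots, targets)))
  verts <- igraph::V(g)$name
  keyOf <- function(s, t) paste(s, t, sep = "\r")
  edgeKeys <- character(); pathList <- list()
  for (t in intersect(targets, verts)) {
    # with several roots, each root's own shortest paths are unioned
    best <- NULL
    for (r in intersect(roots, verts)) {
      sp <- suppressWarnings(
        igraph::all_shortest_paths(g, from = r, to = t, mode = "out"))
      vp <- sp$vpaths %||% sp$res
      if (!length(vp)) next
      best <- c(best, lapply(vp, function(p) verts[as.integer(p)]))
    }
    if (is.null(best)) next
    pathList[[t]] <- best
    for (p in best)
      if (length(p) > 1L)
        edgeKeys <- c(edgeKeys, keyOf(p[-length(p)], p[-1L]))
  }
  reached <- names(pathList)
  newlyExcluded <- setdiff(targets, reached)
  excluded <- rbind(
    if (!is.null(priorExcluded)) priorExcluded,
    if (length(newlyExcluded))
      data.frame(gene = newlyExcluded, reason = "inconsistent",
                 stringsAsFactors = FALSE))
  if (is.null(excluded))
    excluded <- data.frame(gene = character(), reason = character(),
                           stringsAsFactors = FALSE)
  edgeKeys <- unique(edgeKeys)
  keep <- keyOf(edges$source, edges$target) %in% edgeKeys
  finalEdges <- unique(edges[keep, , drop = FALSE])
  nodeIds <- unique(c(unlist(pathList, use.names = FALSE)))
  st <- states[match(nodeIds, states$gene), , drop = FALSE]
  st$gene <- nodeIds  # genes missing from states (shouldn't happen) keep ID
  if (anyNA(st$status)) {
    st$status[is.na(st$status)] <- "no_prediction"
    st$score[is.na(st$score)] <- 0L
  }
  rownames(st) <- NULL; rownames(finalEdges) <- NULL
  new("CausalNetwork", nodes = st, edges = finalEdges,
      excludedTargets = excluded, paths = pathList)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a causal network end to end
#'
#' Convenience pipeline: [restrictToPaths()] then [propagateScores()],
#' [pruneInconsistent()] and [shortestPathNetwork()].
#'
#' @inheritParams propagateScores
#' @param x a \linkS4class{RegulatoryLinks} object or edge data.frame
#' @param targets target genes; defaults to the observed misregulated
#'   genes
#' @return a \linkS4class{CausalNetwork}
#' @export
buildCausalNetwork <- function(x, observed, roots,
                               rootMode = c("knockout", "overexpression"),
                               targets = NULL, maxIter = 100L) {
  rootMode <- match.arg(rootMode)
  obs <- .observedVector(observed)
  if (is.null(targets)) targets <- names(obs)
  sub <- restrictToPaths(x, roots, targets)
  states <- propagateScores(sub, obs, roots, rootMode, maxIter)
  pruned <- pruneInconsistent(sub, states)
  shortestPathNetwork(pruned, states, roots, targets,
                      priorExcluded = sub$excluded)
}

#' Validate predictions against an independent perturbation study
#'
#' Given a study in which a known upstream regulator was induced
#' (overexpression) or silenced (knockout) and the misregulation of a set
#' of genes measured, removes the held-out intermediate genes from the
#' observed input, rebuilds the network and compares each held-out gene's
#' predicted direction with its known direction.
#'
#' @param x a \linkS4class{RegulatoryLinks} object or edge data.frame
#' @param observed observed misregulation (data.frame or named vector);
#'   held-out genes are removed from it automatically
#' @param roots the perturbed regulator(s)
#' @param rootMode "knockout" or "overexpression"
#' @param heldOut named vector of known +1/-1 directions for the
#'   intermediate genes being tested
#' @return list with \code{perGene}: data.frame (gene, known, predicted,
#'   verdict in correct/incorrect/no_prediction, reason) and
#'   \code{summary}: named counts of the three verdicts
#' @export
validateAgainstStudy <- function(x, observed, roots,
                                 rootMode = c("knockout", "overexpression"),
                                 heldOut) {
  rootMode <- match.arg(rootMode)
  obs <- .observedVector(observed)
  held <- .observedVector(heldOut)
  obs <- obs[setdiff(names(obs), names(held))]
  if (!length(obs))
    stop("no observed genes left after removing the held-out set")
  sub <- restrictToPaths(x, roots, names(obs))
  states <- propagateScores(sub, obs, roots, rootMode)
  dir <- setNames(states$direction, states$gene)
  status <- setNames(states$status, states$gene)
  verdict <- character(length(held)); reason <- character(length(held))
  for (i in seq_along(held)) {
    gn <- names(held)[i]
    if (!gn %in% names(dir)) {
      verdict[i] <- "no_prediction"; reason[i] <- "absent_from_subnetwork"
    } else if (is.na(dir[gn]) || status[gn] == "no_prediction") {
      verdict[i] <- "no_prediction"; reason[i] <- "zero_score"
    } else if (dir[gn] == held[i]) {
      verdict[i] <- "correct"; reason[i] <- ""
    } else {
      verdict[i] <- "incorrect"; reason[i] <- ""
    }
  }
  perGene <- data.frame(gene = names(held), known = unname(held),
                        predicted = unname(dir[names(held)]),
                        verdict = verdict, reason = reason,
                        stringsAsFactors = FALSE)
  lv <- c("correct", "incorrect", "no_prediction")
  list(perGene = perGene,
       summary = setNames(as.integer(table(factor(verdict, levels = lv))), lv))
}

#' Write a causal network in simple interaction format
#'
#' Writes \code{<prefix>.sif} (source TAB relation TAB target, relation
#' \code{activates} or \code{represses}), a node-attribute TSV
#' \code{<prefix>.nodes.tsv} (gene, direction, status, score) and an
#' edge-attribute TSV \code{<prefix>.edges.tsv} (source, relation,
#' target, evidence) — all loadable by Cytoscape.
#'
#' @param net a \linkS4class{CausalNetwork}
#' @param prefix output path prefix
#' @return character vector of the files written, invisibly
#' @export
writeSif <- function(net, prefix) {
  stopifnot(is(net, "CausalNetwork"))
  ed <- networkEdges(net)
  relation <- ifelse(ed$sign == 1L, "activates", "represses")
  sif <- paste0(prefix, ".sif")
  write.table(data.frame(ed$source, relation, ed$target), sif,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  nodesFile <- paste0(prefix, ".nodes.tsv")
  write.table(networkNodes(net), nodesFile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  edgesFile <- paste0(prefix, ".edges.tsv")
  write.table(data.frame(source = ed$source, relation = relation,
                         target = ed$target, evidence = ed$evidence),
              edgesFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sif, nodesFile, edgesFile))
}
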