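#' @import methods
#' @importFrom stats setNames phyper pnorm qnorm pchisq chisq.test runif
#'   rnorm aggregate
#' @importFrom utils head read.delim write.table
NULL

.validSigns <- c(-1L, 0L, 1L)

#' RegulatoryLinks: a set of signed, directed regulatory interactions
#'
#' Container for a deduplicated table of directed regulatory links
#' \code{source -> target} with a sign (+1 activation, -1 repression,
#' 0 unknown/"regulates") and a free-text evidence tag. The identity of a
#' link for deduplication purposes is the triple (source, sign, target);
#' evidence tags of collapsed duplicates are ";"-joined.
#'
#' @slot links data.frame with columns \code{source} (character),
#'   \code{sign} (integer in -1/0/+1), \code{target} (character),
#'   \code{evidence} (character).
#' @slot stats list of bookkeeping counters (rows read, duplicates
#'   collapsed, rows skipped, interactions dropped by orthologue mapping).
#'
#' @seealso [loadInteractions()], [filterByEvidence()], [mapOrthologues()]
#' @export
setClass("RegulatoryLinks",
  representation(links = "data.frame", stats = "list"),
  prototype(
    links = data.frame(source = character(), sign = integer(),
                       target = character(), evidence = character(),
                       stringsAsFactors = FALSE),
    stats = list()
  )
)

setValidity("RegulatoryLinks", function(object) {
  lk <- object@links
  need <- c("source", "sign", "target", "evidence")
  if (!all(need %in% names(lk)))
    return(paste("links must have columns", paste(need, collapse = ", ")))
  if (nrow(lk) == 0L) return(TRUE)
  if (any(!lk$sign %in% .validSigns))
    return("sign must be -1, 0 or +1")
  if (any(!nzchar(lk$source)) || any(!nzchar(lk$target)))
    return("source and target gene IDs must be non-empty")
  if (anyDuplicated(lk[, c("source", "sign", "target")]))
    return("duplicate (source, sign, target) triples present")
  TRUE
})

#' CausalNetwork: a consistency-pruned shortest-path explanatory network
#'
#' The end product of sign propagation: the union of all minimum-length
#' directed paths from the root regulator(s) to each reachable misregulated
#' gene, restricted to sign-consistent links, together with per-node
#' predicted/observed directions and the list of targets that could not be
#' included.
#'
#' @slot nodes data.frame with columns \code{gene}, \code{direction}
#'   (integer +1/-1, NA when no prediction), \code{score} (integer),
#'   \code{status} (one of "observed", "predicted", "no_prediction",
#'   "root").
#' @slot edges data.frame with columns \code{source}, \code{sign},
#'   \code{target}, \code{evidence} — a subset of the input links.
#' @slot excludedTargets data.frame with columns \code{gene},
#'   \code{reason} ("no_path" or "inconsistent").
#' @slot paths named list; for each included target, a list of character
#'   vectors, each one shortest root-to-target path (gene IDs in order).
#'
#' @seealso [shortestPathNetwork()], [buildCausalNetwork()], [writeSif()]
#' @export
setClass("CausalNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 excludedTargets = "data.frame", paths = "list"),
  prototype(
    nodes = data.frame(gene = character(), direction = integer(),
                       score = integer(), status = character(),
                       stringsAsFactors = FALSE),
    edges = data.frame(source = character(), sign = integer(),
                       target = character(), evidence = character(),
                       stringsAsFactors = FALSE),
    excludedTargets = data.frame(gene = character(), reason = character(),
                                 stringsAsFactors = FALSE),
    paths = list()
  )
)

setValidity("CausalNetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  if (!all(c("gene", "direction", "score", "status") %in% names(nd)))
    return("nodes must have columns gene, direction, score, status")
  if (!all(c("source", "sign", "target", "evidence") %in% names(ed)))
    return("edges must have columns source, sign, target, evidence")
  if (nrow(ed) > 0L &&
      !all(c(ed$source, ed$target) %in% nd$gene))
    return("every edge endpoint must be a node")
  if (anyDuplicated(nd$gene)) return("duplicate node gene IDs")
  bad <- !nd$status %in% c("observed", "predicted", "no_prediction", "root")
  if (any(bad)) return("unknown node status")
  TRUE
})

#' @describeIn RegulatoryLinks number of links
#' @param x a RegulatoryLinks object
#' @export
setMethod("length", "RegulatoryLinks", function(x) nrow(x@links))

#' Extract the link table from a RegulatoryLinks object
#'
#' @param x a \linkS4class{RegulatoryLinks} object
#' @return data.frame with columns source, sign, target, evidence
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @rdname interactions
#' @export
setMethod("interactions", "RegulatoryLinks", function(x) x@links)

#' Accessors for CausalNetwork components
#'
#' \code{networkNodes} returns the node table (gene, direction, score,
#' status); \code{networkEdges} the retained signed edges;
#' \code{excludedTargets} the misregulated genes that could not be
#' connected to the root, with the reason; \code{networkPaths} the
#' per-target lists of shortest root-to-target paths.
#'
#' @param x a \linkS4class{CausalNetwork}
#' @return a data.frame (or, for \code{networkPaths}, a named list)
#' @name causalnetwork-accessors
NULL

#' @rdname causalnetwork-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname causalnetwork-accessors
#' @export
setMethod("networkNodes", "CausalNetwork", function(x) x@nodes)

#' @rdname causalnetwork-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname causalnetwork-accessors
#' @export
setMethod("networkEdges", "CausalNetwork", function(x) x@edges)

#' @rdname causalnetwork-accessors
#' @export
setGeneric("excludedTargets", function(x) standardGeneric("excludedTargets"))
#' @rdname causalnetwork-accessors
#' @export
setMethod("excludedTargets", "CausalNetwork", function(x) x@excludedTargets)

#' @rdname causalnetwork-accessors
#' @export
setGeneric("networkPaths", function(x) standardGeneric("networkPaths"))
#' @rdname causalnetwork-accessors
#' @export
setMethod("networkPaths", "CausalNetwork", function(x) x@paths)

setMethod("show", "RegulatoryLinks", function(object) {
  lk <- object@links
  cat("RegulatoryLinks with", nrow(lk), "links (",
      sum(lk$sign == 1L), "activating,", sum(lk$sign == -1L),
      "repressing,", sum(lk$sign == 0L), "unsigned )\n")
  st <- object@stats
  if (length(st))
    cat("  stats:", paste(names(st), unlist(st), sep = "=", collapse = ", "),
        "\n")
  if (nrow(lk)) {
    cat("  head:\n")
    print(head(lk, 4L), row.names = FALSE)
  }
  invisible(NULL)
})

setMethod("show", "CausalNetwork", function(object) {
  cat("CausalNetwork:", nrow(object@nodes), "genes,",
      nrow(object@edges), "links\n")
  tab <- table(object@nodes$status)
  cat("  node status:",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  if (nrow(object@excludedTargets))
    cat("  excluded targets:",
        paste(object@excludedTargets$gene, collapse = ", "), "\n")
  invisible(NULL)
})

# internal constructor from a (possibly non-unique) link data.frame
.RegulatoryLinks <- function(links, stats = list()) {
  rownames(links) <- NULL
  links$source <- as.character(links$source)
  links$target <- as.character(links$target)
  links$sign <- as.integer(links$sign)
  links$evidence <- as.character(links$evidence)
  new("RegulatoryLinks", links = links, stats = stats)
}
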