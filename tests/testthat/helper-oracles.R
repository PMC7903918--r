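# Independent brute-force oracles used to check the package's graph and
# counting code. These deliberately share no code with the implementation:
# plain window loops and exhaustive simple-path enumeration.

bruteCountMatches <- function(utr, word) {
  utr <- toupper(utr); word <- toupper(word)
  w <- nchar(word)
  if (nchar(utr) < w) return(0L)
  hits <- 0L
  for (i in seq_len(nchar(utr) - w + 1L))
    if (substr(utr, i, i + w - 1L) == word) hits <- hits + 1L
  hits
}

# adjacency list (unique out-neighbours, self-loops dropped)
.adjList <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    s <- edges$source[i]; t <- edges$target[i]
    if (s != t && !t %in% adj[[s]]) adj[[s]] <- c(adj[[s]], t)
  }
  adj
}

# all simple directed paths s -> t by exhaustive DFS
bruteAllPaths <- function(adj, s, t) {
  res <- list()
  recur <- function(path) {
    last <- path[length(path)]
    if (last == t) { res[[length(res) + 1L]] <<- path; return(invisible()) }
    for (nb in adj[[last]]) if (!nb %in% path) recur(c(path, nb))
  }
  if (s %in% names(adj)) recur(s)
  res
}

bruteShortestPaths <- function(adj, s, t) {
  if (identical(s, t)) return(list())
  p <- bruteAllPaths(adj, s, t)
  if (!length(p)) return(list())
  L <- min(lengths(p))
  p[lengths(p) == L]
}

# normalised directed betweenness by exhaustive shortest-path enumeration
bruteBetweenness <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$source, edges$target)))
  adj <- .adjList(edges, nodes)
  b <- setNames(numeric(length(nodes)), nodes)
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    sp <- bruteShortestPaths(adj, s, t)
    if (!length(sp)) next
    for (v in nodes) {
      if (v == s || v == t) next
      b[v] <- b[v] + mean(vapply(sp, function(p) v %in% p, TRUE))
    }
  }
  n <- length(nodes)
  if (n > 2) b / ((n - 1) * (n - 2)) else b * 0
}

# union of edges on all shortest root->target paths (per root)
bruteShortestPathEdges <- function(edges, roots, targets) {
  nodes <- sort(unique(c(edges$source, edges$target, roots, targets)))
  adj <- .adjList(edges, nodes)
  keys <- character()
  for (r in roots) for (t in setdiff(targets, r)) {
    for (p in bruteShortestPaths(adj, r, t))
      if (length(p) > 1L)
        keys <- c(keys, paste(p[-length(p)], p[-1L], sep = "->"))
  }
  sort(unique(keys))
}

randomDigraph <- function(nNodes, pEdge = 0.3) {
  nodes <- paste0("n", seq_len(nNodes))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < pEdge
  ed <- pairs[keep, , drop = FALSE]
  ed$sign <- sample(c(-1L, 1L), nrow(ed), replace = TRUE)
  ed$evidence <- ""
  rownames(ed) <- NULL
  ed
}

writeTempTsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
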