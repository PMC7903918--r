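## Seeded synthetic-data generators. Each generator draws from its own
## named pseudo-random stream derived from (seed, generator name), so
## adding a generator never perturbs the fixtures of existing ones, and
## identical seeds give byte-identical output.

.streamSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  codes <- utf8ToInt(stream)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 1000003
  as.integer((abs(seed) * 1009 + h * 7919) %% 2147483562)
}

.randomDna <- function(n, lengths) {
  vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

#' Simulate a rooted signed regulatory cascade with planted truth
#'
#' Generates a signed directed acyclic graph rooted at a single regulator
#' whose true misregulation directions are planted top-down: the root is
#' fixed by the perturbation mode (knockout = down), and each child's
#' direction is its parent's direction times the sign of the connecting
#' link along a spanning tree. Extra cross-level edges are added only
#' where consistent with the planted directions, so at zero noise the
#' whole graph is sign-consistent by construction and propagation can
#' recover every internal direction exactly. A fraction of the leaf
#' genes is exported as the "observed" misregulation table, each
#' direction flipped with probability \code{noise}.
#'
#' @param nNodes total number of genes including the root (>= 1)
#' @param depth number of levels below the root (>= 1); must be < nNodes
#' @param signProbs probabilities of link signs (+1, -1, 0). The spanning
#'   tree uses the +1/-1 components (renormalised); the 0 component is
#'   the chance that a cross edge is emitted unsigned ("regulates")
#'   instead of with its consistent sign. Default c(0.5, 0.5, 0).
#' @param crossFrac number of extra cross edges as a fraction of nNodes
#' @param fractionObserved fraction of leaf genes exported as observed
#' @param noise probability that an exported observed direction is
#'   flipped
#' @param rootMode "knockout" (root direction -1) or "overexpression"
#' @param seed integer seed; identical seeds give identical output
#' @return list with \code{links} (\linkS4class{RegulatoryLinks}),
#'   \code{truth} (data.frame gene, direction — planted directions for
#'   every gene), \code{observed} (data.frame gene, direction),
#'   \code{root} (gene ID), \code{leaves} (leaf gene IDs)
#' @export
simulateCascade <- function(nNodes = 200L, depth = 6L,
                            signProbs = c(0.5, 0.5, 0),
                            crossFrac = 0.3,
                            fractionObserved = 1,
                            noise = 0,
                            rootMode = c("knockout", "overexpression"),
                            seed = 1L) {
  rootMode <- match.arg(rootMode)
  stopifnot(length(signProbs) == 3L, all(signProbs >= 0),
            abs(sum(signProbs) - 1) < 1e-8,
            fractionObserved >= 0, fractionObserved <= 1,
            noise >= 0, noise <= 1, nNodes >= 1L)
  rootDir <- if (rootMode == "knockout") -1L else 1L
  root <- "R"
  if (nNodes > 1L && depth >= nNodes)
    stop("depth must be smaller than nNodes")
  if (nNodes == 1L) {
    warning("single-node cascade: root only, no links, nothing observed")
    return(list(
      links = .RegulatoryLinks(
        data.frame(source = character(), sign = integer(),
                   target = character(), evidence = character(),
                   stringsAsFactors = FALSE)),
      truth = data.frame(gene = root, direction = rootDir,
                         stringsAsFactors = FALSE),
      observed = data.frame(gene = character(), direction = integer(),
                            stringsAsFactors = FALSE),
      root = root, leaves = character()))
  }
  withr::with_seed(.streamSeed(seed, "cascade"), {
    ids <- sprintf("G%04d", seq_len(nNodes - 1L))
    # levels 1..depth, each level non-empty where possible
    level <- sort(c(seq_len(min(depth, nNodes - 1L)),
                    if (nNodes - 1L > depth)
                      sample(seq_len(depth), nNodes - 1L - depth,
                             replace = TRUE)))
    nodeLevel <- c(0L, level)
    names(nodeLevel) <- c(root, ids)
    pTree <- signProbs[1:2] / sum(signProbs[1:2])
    parent <- character(nNodes - 1L)
    for (i in seq_along(ids)) {
      cand <- names(nodeLevel)[nodeLevel == level[i] - 1L]
      parent[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    }
    treeSign <- sample(c(1L, -1L), nNodes - 1L, replace = TRUE, prob = pTree)
    dir <- setNames(integer(nNodes), names(nodeLevel))
    dir[root] <- rootDir
    for (i in order(level)) dir[ids[i]] <- dir[parent[i]] * treeSign[i]
    edges <- data.frame(source = parent, sign = treeSign, target = ids,
                        evidence = "sim-tree", stringsAsFactors = FALSE)
    nCross <- round(crossFrac * nNodes)
    if (nCross > 0L) {
      all <- names(nodeLevel)
      u <- sample(all, nCross * 4L, replace = TRUE)
      v <- sample(all, nCross * 4L, replace = TRUE)
      ok <- nodeLevel[u] < nodeLevel[v]
      u <- u[ok]; v <- v[ok]
      if (length(u)) {
        keep <- !duplicated(paste(u, v)) &
          !(paste(u, v) %in% paste(edges$source, edges$target))
        u <- head(u[keep], nCross); v <- head(v[keep], nCross)
        if (length(u)) {
          s <- as.integer(dir[u] * dir[v])  # consistent by construction
          unsigned <- runif(length(u)) < signProbs[3L]
          s[unsigned] <- 0L
          edges <- rbind(edges,
                         data.frame(source = u, sign = s, target = v,
                                    evidence = "sim-cross",
                                    stringsAsFactors = FALSE))
        }
      }
    }
    leaves <- setdiff(names(nodeLevel), edges$source)
    nObs <- round(fractionObserved * length(leaves))
    obsGenes <- if (nObs >= length(leaves)) leaves
                else sort(sample(leaves, nObs))
    obsDir <- dir[obsGenes]
    flip <- runif(length(obsGenes)) < noise
    obsDir[flip] <- -obsDir[flip]
    list(
      links = .RegulatoryLinks(edges),
      truth = data.frame(gene = names(dir), direction = unname(dir),
                         stringsAsFactors = FALSE),
      observed = data.frame(gene = obsGenes, direction = unname(obsDir),
                            stringsAsFactors = FALSE),
      root = root, leaves = leaves)
  })
}

#' Simulate a 3'UTR sequence set with optional planted word
#'
#' Uniform-random DNA sequences with lengths drawn uniformly from
#' \code{lengthRange}; when a word is planted, it overwrites the sequence
#' at one random position per planted gene, and the insertion positions
#' are returned so expected minimum match counts are known.
#'
#' @param nGenes number of genes (one record per gene, named
#'   \code{g0001} ...)
#' @param lengthRange integer length range \code{c(min, max)}
#' @param planted optional word (e.g. a seed complement) to insert
#' @param plantedGenes gene names receiving the planted word (default:
#'   none)
#' @param seed integer seed
#' @return list with \code{utrs} (\code{DNAStringSet}) and
#'   \code{plantLog} (data.frame gene, position; empty when nothing
#'   planted)
#' @export
simulateUtrSet <- function(nGenes, lengthRange = c(50L, 300L),
                           planted = NULL, plantedGenes = character(),
                           seed = 1L) {
  stopifnot(nGenes >= 1L, length(lengthRange) == 2L,
            lengthRange[1L] <= lengthRange[2L])
  if (!is.null(planted) && lengthRange[1L] < nchar(planted))
    stop("minimum UTR length is shorter than the planted word")
  withr::with_seed(.streamSeed(seed, "utrs"), {
    genes <- sprintf("g%04d", seq_len(nGenes))
    lens <- sample(seq(lengthRange[1L], lengthRange[2L]), nGenes,
                   replace = TRUE)
    seqs <- .randomDna(nGenes, lens)
    plantLog <- data.frame(gene = character(), position = integer(),
                           stringsAsFactors = FALSE)
    if (!is.null(planted) && length(plantedGenes)) {
      w <- nchar(planted)
      idx <- match(plantedGenes, genes)
      if (anyNA(idx)) stop("plantedGenes not in the generated gene set")
      pos <- vapply(lens[idx], function(L) sample(L - w + 1L, 1L), 0L)
      for (j in seq_along(idx))
        substr(seqs[idx[j]], pos[j], pos[j] + w - 1L) <- planted
      plantLog <- data.frame(gene = plantedGenes, position = pos,
                             stringsAsFactors = FALSE)
    }
    utrs <- Biostrings::DNAStringSet(setNames(seqs, genes))
    list(utrs = utrs, plantLog = plantLog)
  })
}

#' Simulate a ranked gene list with bin-concentrated word enrichment
#'
#' Generates a ranked gene list (most upregulated first, with a
#' monotonically decreasing rank statistic) and matching UTRs in which a
#' chosen word is planted preferentially in the top fraction of the
#' ranking, so a word-enrichment landscape over cumulative leading bins
#' shows its peak within the top-fraction bins. With
#' \code{topFraction = 1} planting is uniform over the whole ranking and
#' carries no positional signal.
#'
#' @param nGenes number of ranked genes
#' @param enrichedHeptamer the word to plant
#' @param topFraction fraction of the ranking receiving preferential
#'   planting, in (0, 1]
#' @param plantProb probability that a top-fraction gene receives one
#'   planted copy (default 0.9)
#' @param lengthRange UTR length range
#' @param seed integer seed
#' @return list with \code{ranked} (data.frame gene, stat, in rank
#'   order), \code{utrs} (\code{DNAStringSet}) and \code{plantLog}
#' @export
simulateRankedList <- function(nGenes, enrichedHeptamer,
                               topFraction = 0.1, plantProb = 0.9,
                               lengthRange = c(50L, 300L), seed = 1L) {
  stopifnot(topFraction > 0, topFraction <= 1, nGenes >= 1L)
  withr::with_seed(.streamSeed(seed, "ranked"), {
    genes <- sprintf("g%04d", seq_len(nGenes))
    stat <- sort(rnorm(nGenes), decreasing = TRUE)
    nTop <- max(1L, round(topFraction * nGenes))
    plantedGenes <- genes[seq_len(nTop)][runif(nTop) < plantProb]
    plantSeed <- sample.int(2147483562L, 1L)
  })
  utr <- simulateUtrSet(nGenes, lengthRange, planted = enrichedHeptamer,
                        plantedGenes = plantedGenes, seed = plantSeed)
  list(ranked = data.frame(gene = genes, stat = stat,
                           stringsAsFactors = FALSE),
       utrs = utr$utrs, plantLog = utr$plantLog)
}
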