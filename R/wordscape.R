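#' Build a ranked word universe from a gene ranking and UTR sequences
#'
#' Tokenises each ranked gene's 3'UTR(s) into overlapping words of length
#' \code{wordLen} (a UTR of length L contributes max(0, L - wordLen + 1)
#' word tokens; multiple records per gene are summed). The universe is
#' defined over word positions (tokens), not gene presence/absence. Genes
#' in the ranking without any UTR record are dropped with a warning.
#'
#' @param rankedGenes character vector of gene IDs ordered from most
#'   upregulated to most downregulated (no duplicates)
#' @param utrs \code{DNAStringSet} or FASTA path; headers parsed as in
#'   [scanSeedMatches()]
#' @param wordLen word length in nucleotides (default 7)
#' @param geneIdPattern regex with one capture group for the gene ID
#' @return object of class \code{wordUniverse}: list with \code{genes}
#'   (ranked gene IDs retained), \code{counts} (integer matrix, genes x
#'   4^wordLen words, overlapping-window counts), \code{wordsPerGene}
#'   (tokens contributed by each gene), \code{N} (total tokens) and
#'   \code{K} (per-word universe counts)
#' @export
buildWordUniverse <- function(rankedGenes, utrs, wordLen = 7L,
                              geneIdPattern = "^\\s*([^|[:space:]]+)") {
  if (is.character(utrs) && length(utrs) == 1L && file.exists(utrs))
    utrs <- Biostrings::readDNAStringSet(utrs)
  stopifnot(is(utrs, "DNAStringSet"), wordLen >= 1L)
  rankedGenes <- as.character(rankedGenes)
  if (anyDuplicated(rankedGenes))
    stop("ranked gene list contains duplicate IDs")
  gene <- sub(paste0(geneIdPattern, ".*$"), "\\1", names(utrs))
  keepRec <- gene %in% rankedGenes
  if (!any(keepRec))
    stop("no overlap between the ranking and the UTR set")
  utrs <- utrs[keepRec]; gene <- gene[keepRec]
  missing <- setdiff(rankedGenes, gene)
  if (length(missing))
    warning(length(missing), " ranked gene(s) without UTR sequence dropped")
  genes <- rankedGenes[rankedGenes %in% gene]
  # overlapping windows over every record, summed within gene
  freq <- Biostrings::oligonucleotideFrequency(utrs, width = wordLen,
                                               step = 1L)
  counts <- rowsum(freq, group = factor(gene, levels = genes))
  storage.mode(counts) <- "integer"
  wordsPerGene <- as.integer(rowSums(counts))
  structure(list(genes = genes, counts = counts,
                 wordsPerGene = setNames(wordsPerGene, genes),
                 N = sum(wordsPerGene),
                 K = colSums(counts)),
            class = "wordUniverse")
}

#' @export
print.wordUniverse <- function(x, ...) {
  cat("wordUniverse:", length(x$genes), "ranked genes,",
      ncol(x$counts), "words of length", nchar(colnames(x$counts)[1L]),
      "\n  total word tokens N =", x$N, "; words present =",
      sum(x$K > 0), "\n")
  invisible(x)
}

#' Hypergeometric enrichment/depletion landscape over cumulative bins
#'
#' For cumulative leading bins of the ranking (the first
#' \code{binStep} genes, the first 2*\code{binStep}, ..., up to all
#' genes), tests every word for enrichment and depletion among the bin's
#' UTR word tokens against the whole-universe word frequencies, under
#' Hypergeometric(N, K_w, n): \code{pEnrich = P[X >= x]},
#' \code{pDeplete = P[X <= x]}, where x is the word's token count in the
#' bin and n the bin's total tokens. The signed display score is
#' \code{-log10(pEnrich)} when enrichment is the smaller tail (positive =
#' enriched) and \code{log10(pDeplete)} otherwise (negative = depleted).
#' The final bin equals the universe, so every score there is exactly 0.
#' Raw (uncorrected) p-values are reported; a Bonferroni guide level over
#' all 4^wordLen words is returned as an attribute for annotation.
#'
#' @param universe a \code{wordUniverse} from [buildWordUniverse()]
#' @param binStep genes added per bin (default 500); a step larger than
#'   the universe yields the single full-universe bin with a warning
#' @return data.frame (class \code{wordLandscape}) with columns
#'   \code{word}, \code{bin} (number of leading genes), \code{x},
#'   \code{n}, \code{K}, \code{pEnrich}, \code{pDeplete},
#'   \code{signedScore}; attribute \code{bonferroni} holds the
#'   -log10(0.05 / 4^wordLen) guide value, attribute \code{N} the universe
#'   token total
#' @export
wordLandscape <- function(universe, binStep = 500L) {
  stopifnot(inherits(universe, "wordUniverse"), binStep >= 1L)
  nGenes <- length(universe$genes)
  if (binStep > nGenes) {
    warning("binStep exceeds the number of genes; single full-universe bin")
    bins <- nGenes
  } else {
    bins <- seq(binStep, nGenes, by = binStep)
    if (bins[length(bins)] != nGenes) bins <- c(bins, nGenes)
  }
  N <- universe$N
  K <- universe$K
  words <- colnames(universe$counts)
  cells <- vector("list", length(bins))
  acc <- rep(0L, length(K))
  prev <- 0L
  for (i in seq_along(bins)) {
    b <- bins[i]
    block <- universe$counts[seq.int(prev + 1L, b), , drop = FALSE]
    acc <- acc + colSums(block)
    prev <- b
    n <- sum(universe$wordsPerGene[seq_len(b)])
    x <- acc
    # log-scale tails keep scores finite even for extreme enrichment
    logEnrich <- phyper(x - 1L, K, N - K, n, lower.tail = FALSE,
                        log.p = TRUE)
    logDeplete <- phyper(x, K, N - K, n, lower.tail = TRUE, log.p = TRUE)
    score <- ifelse(logEnrich <= logDeplete,
                    -logEnrich / log(10), logDeplete / log(10))
    cells[[i]] <- data.frame(word = words, bin = b, x = as.integer(x),
                             n = n, K = as.integer(K),
                             pEnrich = exp(logEnrich),
                             pDeplete = exp(logDeplete),
                             signedScore = score,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  attr(out, "bonferroni") <- -log10(0.05 / length(words))
  attr(out, "N") <- N
  class(out) <- c("wordLandscape", "data.frame")
  out
}

#' Words with the highest and lowest landscape peaks
#'
#' Returns the \code{k} words whose maximum signed score across bins is
#' largest (enrichment peaks) and the \code{k} whose minimum signed score
#' is smallest (depletion troughs), plus any user-supplied words (e.g.
#' seed complements) for annotation.
#'
#' @param cells a \code{wordLandscape} from [wordLandscape()]
#' @param k number of peaks/troughs to return (k = 0 returns only the
#'   annotated words)
#' @param annotate character vector of words always included
#' @return data.frame with columns \code{word}, \code{role} ("peak",
#'   "trough" or "annotated"), \code{peakScore} (the signed score of the
#'   word's extreme bin) and \code{peakBin}
#' @export
topHeptamers <- function(cells, k = 3L, annotate = character()) {
  stopifnot(inherits(cells, "data.frame"), k >= 0L)
  byWord <- split(seq_len(nrow(cells)), cells$word)
  stat <- t(vapply(byWord, function(i) {
    s <- cells$signedScore[i]
    c(max = max(s), min = min(s),
      binMax = cells$bin[i][which.max(s)],
      binMin = cells$bin[i][which.min(s)])
  }, c(max = 0, min = 0, binMax = 0, binMin = 0)))
  words <- rownames(stat)
  peaks <- words[order(stat[, "max"], decreasing = TRUE)][seq_len(min(k, length(words)))]
  troughs <- words[order(stat[, "min"])][seq_len(min(k, length(words)))]
  rows <- list()
  if (length(peaks))
    rows$peak <- data.frame(word = peaks, role = "peak",
                            peakScore = stat[peaks, "max"],
                            peakBin = stat[peaks, "binMax"])
  if (length(troughs))
    rows$trough <- data.frame(word = troughs, role = "trough",
                              peakScore = stat[troughs, "min"],
                              peakBin = stat[troughs, "binMin"])
  annotate <- intersect(toupper(annotate), words)
  if (length(annotate))
    rows$annot <- data.frame(word = annotate, role = "annotated",
                             peakScore = stat[annotate, "max"],
                             peakBin = stat[annotate, "binMax"])
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(word = character(), role = character(),
                      peakScore = numeric(), peakBin = numeric())
  rownames(out) <- NULL
  out
}

#' Write a landscape to long-format TSV
#'
#' One row per (word, bin): word, bin, x, n, signedScore — ready for
#' plotting.
#'
#' @param cells a \code{wordLandscape}
#' @param path output TSV path
#' @return \code{path}, invisibly
#' @export
writeLandscape <- function(cells, path) {
  write.table(cells[, c("word", "bin", "x", "n", "signedScore")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
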