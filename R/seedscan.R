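#' Seed-complement heptamer of a mature miRNA
#'
#' The seed region of a mature miRNA is bases 2-8 (1-based, inclusive) of
#' its sequence; target sites in 3'UTRs are matches to the reverse
#' complement of the seed, in DNA alphabet. For miR-96
#' (UUUGGCACUAGCACAUUUUUGCU) the seed UUGGCAC gives the seed complement
#' GTGCCAA.
#'
#' @param matureSeq mature miRNA sequence, RNA alphabet (A, C, G, U;
#'   lower case accepted)
#' @param seedStart 1-based start of the seed region (default 2)
#' @param seedLen seed length (default 7)
#' @return the DNA-alphabet reverse complement of the seed, as a character
#'   string of length \code{seedLen}
#' @export
#' @examples
#' seedComplement("UUUGGCACUAGCACAUUUUUGCU")  # "GTGCCAA"
seedComplement <- function(matureSeq, seedStart = 2L, seedLen = 7L) {
  matureSeq <- toupper(as.character(matureSeq))
  if (grepl("[^ACGU]", matureSeq))
    stop("mature sequence must be RNA over {A,C,G,U}: ", matureSeq)
  if (nchar(matureSeq) < seedStart - 1L + seedLen)
    stop("mature sequence shorter than seed region (need >= ",
         seedStart - 1L + seedLen, " nt, got ", nchar(matureSeq), ")")
  seed <- Biostrings::subseq(Biostrings::RNAString(matureSeq),
                             start = seedStart, width = seedLen)
  as.character(Biostrings::DNAString(Biostrings::reverseComplement(seed)))
}

#' Count occurrences of a seed-complement heptamer in a 3'UTR
#'
#' Sliding-window count of exact matches; overlapping occurrences are
#' counted. Comparison is case-insensitive; \code{N} bases never match. A
#' UTR shorter than the word is not an error and yields 0.
#'
#' @param utr DNA string over {A,C,G,T,N}
#' @param heptamer word to count (any length >= 1; typically the
#'   7-mer from [seedComplement()])
#' @return non-negative integer match count
#' @export
countSeedMatches <- function(utr, heptamer) {
  utr <- toupper(as.character(utr))
  heptamer <- toupper(as.character(heptamer))
  if (nchar(utr) < nchar(heptamer)) return(0L)
  # fixed = TRUE: no IUPAC wildcard expansion, so N never matches ACGT
  Biostrings::countPattern(heptamer, Biostrings::DNAString(utr),
                           fixed = TRUE)
}

#' Count seed matches per gene over a UTR FASTA
#'
#' Counts matches of each seed-complement word in every UTR record and
#' sums counts over all records (isoforms) sharing a gene ID. FASTA
#' headers are parsed as \code{geneID} or \code{geneID|transcriptID}; the
#' gene-ID capture is configurable by regex.
#'
#' @param utrs a \code{DNAStringSet} (e.g. from
#'   \code{Biostrings::readDNAStringSet}) or the path to a UTR FASTA file
#' @param heptamers named character vector of words; names are the miRNA
#'   (or word) labels reported in the output
#' @param geneIdPattern regex with one capture group extracting the gene
#'   ID from a FASTA header
#' @return list with \code{perGene}: data.frame(gene, mirna, count) summed
#'   over isoforms, and \code{perRecord}: the per-FASTA-record breakdown
#'   (record, gene, mirna, count)
#' @export
scanSeedMatches <- function(utrs, heptamers,
                            geneIdPattern = "^\\s*([^|[:space:]]+)") {
  if (is.character(utrs) && length(utrs) == 1L && file.exists(utrs))
    utrs <- Biostrings::readDNAStringSet(utrs)
  stopifnot(is(utrs, "DNAStringSet"))
  if (is.null(names(heptamers)))
    names(heptamers) <- as.character(heptamers)
  gene <- sub(paste0(geneIdPattern, ".*$"), "\\1", names(utrs))
  perRecord <- do.call(rbind, lapply(seq_along(heptamers), function(i) {
    counts <- Biostrings::vcountPattern(toupper(heptamers[[i]]), utrs,
                                        fixed = TRUE)
    data.frame(record = names(utrs), gene = gene,
               mirna = names(heptamers)[i], count = counts,
               stringsAsFactors = FALSE)
  }))
  agg <- aggregate(count ~ gene + mirna, data = perRecord, FUN = sum)
  agg <- agg[order(agg$mirna, agg$gene), c("gene", "mirna", "count")]
  rownames(agg) <- NULL
  list(perGene = agg, perRecord = perRecord)
}

.strainCategories <- c("same_count", "both_present_different_count",
                       "only_in_A", "only_in_B", "absent_in_both",
                       "missing_utr_A", "missing_utr_B", "missing_utr_both")

#' Compare per-gene seed-match counts between two strains
#'
#' For every gene with a shared (MGI-style) identifier, classifies the
#' pair of per-strain seed-match counts into exactly one category:
#' \code{same_count} (both strains have the same non-zero count),
#' \code{absent_in_both}, \code{both_present_different_count},
#' \code{only_in_A} / \code{only_in_B} (matches in one strain only), or a
#' \code{missing_utr_*} category when a strain has no UTR sequence for the
#' gene. Genes without a shared identifier must be removed before calling
#' (no cross-strain correspondence can be established for them).
#'
#' @param countsA,countsB named integer vectors of per-gene match counts
#'   for the two strains; a gene absent from a vector is treated as having
#'   no UTR sequence available in that strain
#' @param genes optional character vector fixing the gene universe;
#'   default is the union of the two names
#' @return list with \code{perGene}: data.frame(gene, countA, countB,
#'   category), and \code{summary}: named integer vector of counts per
#'   category (all categories present, zero-filled)
#' @export
compareStrains <- function(countsA, countsB, genes = NULL) {
  stopifnot(!is.null(names(countsA)), !is.null(names(countsB)))
  if (is.null(genes)) genes <- union(names(countsA), names(countsB))
  a <- countsA[genes]; b <- countsB[genes]
  availA <- !is.na(a); availB <- !is.na(b)
  category <- character(length(genes))
  category[!availA & !availB] <- "missing_utr_both"
  category[!availA & availB] <- "missing_utr_A"
  category[availA & !availB] <- "missing_utr_B"
  both <- availA & availB
  category[both & a == 0 & b == 0] <- "absent_in_both"
  category[both & a > 0 & b == 0] <- "only_in_A"
  category[both & a == 0 & b > 0] <- "only_in_B"
  category[both & a > 0 & b > 0 & a == b] <- "same_count"
  category[both & a > 0 & b > 0 & a != b] <- "both_present_different_count"
  perGene <- data.frame(gene = genes, countA = unname(a), countB = unname(b),
                        category = category, stringsAsFactors = FALSE)
  summary <- table(factor(category, levels = .strainCategories))
  list(perGene = perGene,
       summary = setNames(as.integer(summary), .strainCategories))
}

#' End-to-end strain comparison from UTR FASTA files
#'
#' Scans both strains' UTR sets for the same seed-complement word(s),
#' sums counts per gene and classifies every gene in the union of the two
#' gene sets with [compareStrains()].
#'
#' @param utrsA,utrsB \code{DNAStringSet}s or FASTA paths for the two
#'   strains
#' @param heptamer a single seed-complement word
#' @param geneIdPattern see [scanSeedMatches()]
#' @return as [compareStrains()]
#' @export
compareStrainUtrs <- function(utrsA, utrsB, heptamer,
                              geneIdPattern = "^\\s*([^|[:space:]]+)") {
  hs <- setNames(heptamer[1L], "seed")
  cA <- scanSeedMatches(utrsA, hs, geneIdPattern)$perGene
  cB <- scanSeedMatches(utrsB, hs, geneIdPattern)$perGene
  compareStrains(setNames(cA$count, cA$gene), setNames(cB$count, cB$gene))
}
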