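#' Default interaction-word to sign vocabulary
#'
#' Maps the free-text interaction word of an interaction table to a
#' regulation sign. Matching is case-insensitive; words not in the
#' vocabulary are mapped to sign 0 ("regulates", direction unknown) with a
#' warning, so that unsigned literature links are retained for
#' connectivity but never contribute to sign propagation.
#'
#' @return named integer vector (names are lower-case interaction words)
#' @export
#' @examples
#' defaultSignVocabulary()
defaultSignVocabulary <- function() {
  c(activates = 1L, upregulates = 1L,
    represses = -1L, inhibits = -1L, downregulates = -1L,
    regulates = 0L)
}

.trim <- function(x) gsub("^\\s+|\\s+$", "", x)

# collapse exact (source, sign, target) duplicates; ";"-join unique evidence
.dedupe <- function(links) {
  key <- paste(links$source, links$sign, links$target, sep = "\r")
  if (!anyDuplicated(key)) {
    links$evidence[is.na(links$evidence)] <- ""
    return(list(links = links, duplicates = 0L))
  }
  ev <- split(links$evidence, factor(key, levels = unique(key)))
  ev <- vapply(ev, function(e) {
    e <- unique(e[!is.na(e) & nzchar(e)])
    paste(e, collapse = ";")
  }, character(1))
  first <- !duplicated(key)
  out <- links[first, , drop = FALSE]
  out$evidence <- as.character(ev)
  list(links = out, duplicates = sum(!first))
}

#' Read and merge regulatory-interaction tables
#'
#' Reads one or more tab-separated interaction tables with columns
#' \code{source, interaction-word, target[, evidence]}, maps interaction
#' words to signs through \code{signVocabulary}, trims whitespace around
#' gene IDs (IDs are otherwise compared case-sensitively) and collapses
#' exact (source, sign, target) duplicates, ";"-joining their evidence
#' tags. Lines starting with \code{#} are ignored. Rows with fewer than
#' three fields or empty gene IDs are skipped with a warning, never
#' silently.
#'
#' @param paths character vector of TSV file paths
#' @param signVocabulary named integer vector mapping lower-case
#'   interaction words to signs; see [defaultSignVocabulary()]
#' @param normaliseIds optional function applied to every gene ID (e.g. a
#'   symbol-casing normaliser); default \code{NULL} leaves IDs untouched
#' @return a \linkS4class{RegulatoryLinks} object; its \code{stats} record
#'   rows read, duplicates collapsed and rows skipped
#' @export
loadInteractions <- function(paths, signVocabulary = defaultSignVocabulary(),
                             normaliseIds = NULL) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("interaction file(s) not found: ", paste(missing, collapse = ", "))
  rows <- list()
  nRead <- 0L; nSkipped <- 0L
  for (p in paths) {
    lines <- readLines(p, warn = FALSE)
    lines <- lines[!grepl("^\\s*#", lines)]
    lines <- lines[nzchar(.trim(lines))]
    if (!length(lines)) {
      warning("no interaction rows in ", p)
      next
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nRead <- nRead + length(fields)
    ok <- lengths(fields) >= 3L
    if (any(!ok)) {
      warning(sum(!ok), " malformed row(s) skipped in ", p,
              " (fewer than 3 tab-separated fields)")
      nSkipped <- nSkipped + sum(!ok)
      fields <- fields[ok]
    }
    if (!length(fields)) next
    src <- .trim(vapply(fields, `[`, "", 1L))
    word <- tolower(.trim(vapply(fields, `[`, "", 2L)))
    tgt <- .trim(vapply(fields, `[`, "", 3L))
    ev <- .trim(vapply(fields, function(f)
      if (length(f) >= 4L) f[4L] else "", ""))
    bad <- !nzchar(src) | !nzchar(tgt)
    if (any(bad)) {
      warning(sum(bad), " row(s) with empty gene ID skipped in ", p)
      nSkipped <- nSkipped + sum(bad)
    }
    keep <- !bad
    rows[[p]] <- data.frame(source = src[keep], word = word[keep],
                            target = tgt[keep], evidence = ev[keep],
                            stringsAsFactors = FALSE)
  }
  if (!length(rows) || !sum(vapply(rows, nrow, 0L))) {
    return(.RegulatoryLinks(
      data.frame(source = character(), sign = integer(),
                 target = character(), evidence = character(),
                 stringsAsFactors = FALSE),
      stats = list(rowsRead = nRead, duplicates = 0L, skipped = nSkipped)))
  }
  tab <- do.call(rbind, rows)
  names(signVocabulary) <- tolower(names(signVocabulary))
  sign <- unname(signVocabulary[tab$word])
  unknown <- is.na(sign)
  if (any(unknown)) {
    warning(sum(unknown), " interaction row(s) with unknown word(s) ",
            paste(unique(tab$word[unknown]), collapse = ", "),
            " mapped to sign 0")
    sign[unknown] <- 0L
  }
  links <- data.frame(source = tab$source, sign = as.integer(sign),
                      target = tab$target, evidence = tab$evidence,
                      stringsAsFactors = FALSE)
  if (!is.null(normaliseIds)) {
    links$source <- normaliseIds(links$source)
    links$target <- normaliseIds(links$target)
  }
  dd <- .dedupe(links)
  if (dd$duplicates > 0L)
    message(dd$duplicates, " duplicate link(s) collapsed")
  .RegulatoryLinks(dd$links,
                   stats = list(rowsRead = nRead, duplicates = dd$duplicates,
                                skipped = nSkipped))
}

#' Keep only interactions with a given evidence class
#'
#' Retains interactions whose evidence tag contains (case-insensitive
#' substring match) any of the allowed evidence classes, e.g. keeping only
#' targets backed by strong experimental evidence such as reporter assays
#' or western blotting. Input order is preserved; an empty result is
#' permitted.
#'
#' @param x a \linkS4class{RegulatoryLinks} object
#' @param allowed non-empty character vector of evidence classes
#' @return a filtered \linkS4class{RegulatoryLinks} object
#' @export
filterByEvidence <- function(x, allowed) {
  stopifnot(is(x, "RegulatoryLinks"))
  if (!length(allowed) || !any(nzchar(allowed)))
    stop("'allowed' evidence classes must be non-empty")
  ev <- tolower(x@links$evidence)
  keep <- Reduce(`|`, lapply(tolower(allowed), function(a)
    grepl(a, ev, fixed = TRUE)))
  .RegulatoryLinks(x@links[keep, , drop = FALSE],
                   stats = c(x@stats, list(evidenceFiltered = sum(!keep))))
}

#' Read an orthologue mapping table
#'
#' One row per (foreign ID, native ID) pair, tab-separated, \code{#}
#' comments ignored. A foreign ID mapping to exactly one native ID is a
#' one-to-one orthologue; others are ambiguous.
#'
#' @param path TSV file path with columns foreign_id, native_id
#' @return named list: for each foreign ID, the character vector of native
#'   IDs it maps to
#' @export
readOrthologueMap <- function(path) {
  if (!file.exists(path)) stop("orthologue map not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(.trim(lines))]
  if (!length(lines)) return(structure(list(), names = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 2L
  if (any(!ok)) warning(sum(!ok), " malformed orthologue row(s) skipped")
  foreign <- .trim(vapply(fields[ok], `[`, "", 1L))
  native <- .trim(vapply(fields[ok], `[`, "", 2L))
  lapply(split(native, factor(foreign, levels = unique(foreign))), unique)
}

#' Convert interaction endpoints across species via one-to-one orthologues
#'
#' Endpoints found in the map with exactly one native ID are renamed;
#' interactions with an endpoint that maps ambiguously (2+ native IDs) or
#' to nothing are dropped and counted. Endpoints absent from the map are
#' treated as already native and pass through unchanged (the typical use
#' case maps a minority of foreign IDs into an otherwise-native gene set).
#'
#' @param x a \linkS4class{RegulatoryLinks} object
#' @param map orthologue map as returned by [readOrthologueMap()]
#' @return a \linkS4class{RegulatoryLinks} object; \code{stats$orthologueDropped}
#'   counts dropped interactions
#' @export
mapOrthologues <- function(x, map) {
  stopifnot(is(x, "RegulatoryLinks"))
  lk <- x@links
  if (!nrow(lk) || !length(map))
    return(.RegulatoryLinks(lk, stats = c(x@stats, list(orthologueDropped = 0L))))
  n <- lengths(map)
  one2one <- unlist(map[n == 1L], use.names = FALSE)
  names(one2one) <- names(map)[n == 1L]
  ambiguous <- names(map)[n != 1L]
  rename <- function(ids) {
    hit <- ids %in% names(one2one)
    ids[hit] <- unname(one2one[ids[hit]])
    ids
  }
  drop <- lk$source %in% ambiguous | lk$target %in% ambiguous
  lk <- lk[!drop, , drop = FALSE]
  lk$source <- rename(lk$source)
  lk$target <- rename(lk$target)
  dd <- .dedupe(lk)  # renaming can create new coincident triples
  .RegulatoryLinks(dd$links,
                   stats = c(x@stats, list(orthologueDropped = sum(drop))))
}

#' Read a misregulation table
#'
#' Tab-separated columns: gene, direction (\code{up}, \code{down},
#' \code{+1}, \code{-1}, or a signed number such as a log-fold-change),
#' optional logFC, optional FDR. Direction 0 is invalid: only genes with a
#' definite direction of misregulation belong in this table.
#'
#' @param path TSV file path
#' @param fdrMax optional FDR cutoff; rows above it are dropped
#' @return data.frame with columns gene, direction (integer +1/-1),
#'   logFC (numeric or NA), fdr (numeric or NA)
#' @export
readMisregulation <- function(path, fdrMax = NULL) {
  if (!file.exists(path)) stop("misregulation table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(.trim(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 2L
  if (any(!ok)) warning(sum(!ok), " malformed misregulation row(s) skipped")
  fields <- fields[ok]
  gene <- .trim(vapply(fields, `[`, "", 1L))
  dirRaw <- tolower(.trim(vapply(fields, `[`, "", 2L)))
  dir <- ifelse(dirRaw %in% c("up", "+1", "1"), 1L,
         ifelse(dirRaw %in% c("down", "-1"), -1L,
                sign(suppressWarnings(as.numeric(dirRaw)))))
  bad <- is.na(dir) | dir == 0L
  if (any(bad)) {
    warning(sum(bad), " row(s) with undefined direction skipped")
    gene <- gene[!bad]; dir <- dir[!bad]; fields <- fields[!bad]
  }
  num <- function(i) vapply(fields, function(f)
    if (length(f) >= i) suppressWarnings(as.numeric(f[i])) else NA_real_, 0)
  out <- data.frame(gene = gene, direction = as.integer(dir),
                    logFC = num(3L), fdr = num(4L),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene)) {
    warning("duplicate gene IDs in misregulation table; keeping first")
    out <- out[!duplicated(out$gene), , drop = FALSE]
  }
  if (!is.null(fdrMax)) out <- out[!is.na(out$fdr) & out$fdr < fdrMax, ]
  rownames(out) <- NULL
  out
}

#' Derive miRNA-to-target repression edges from seed matches
#'
#' Genes upregulated in a miRNA-knockout transcriptome that carry at least
#' one match to the miRNA's seed complement in their 3'UTR are included as
#' (derepressed) targets: one repressive edge per (miRNA, gene) pair is
#' emitted regardless of the number of matches. Down-regulated genes never
#' yield target edges.
#'
#' @param misregulation data.frame as from [readMisregulation()]; only
#'   rows with \code{direction == +1} are considered
#' @param seedHits data.frame of per-gene seed-match counts with columns
#'   \code{gene}, \code{mirna}, \code{count} (as produced by
#'   [scanSeedMatches()])
#' @param evidence evidence tag recorded on the derived edges
#' @return a \linkS4class{RegulatoryLinks} object of repressive
#'   miRNA-to-gene edges
#' @export
addMirnaTargetEdges <- function(misregulation, seedHits,
                                evidence = "seed-match") {
  stopifnot(all(c("gene", "direction") %in% names(misregulation)),
            all(c("gene", "mirna", "count") %in% names(seedHits)))
  up <- misregulation$gene[misregulation$direction == 1L]
  hit <- seedHits[seedHits$count >= 1L & seedHits$gene %in% up, , drop = FALSE]
  links <- unique(data.frame(source = as.character(hit$mirna), sign = -1L,
                             target = as.character(hit$gene),
                             evidence = evidence, stringsAsFactors = FALSE))
  .RegulatoryLinks(links)
}

#' Concatenate sets of regulatory links
#'
#' Merges link tables and re-deduplicates on (source, sign, target),
#' ";"-joining evidence.
#'
#' @param ... \linkS4class{RegulatoryLinks} objects
#' @return a merged \linkS4class{RegulatoryLinks} object
#' @export
mergeInteractions <- function(...) {
  objs <- list(...)
  stopifnot(all(vapply(objs, is, TRUE, "RegulatoryLinks")))
  lk <- do.call(rbind, lapply(objs, interactions))
  dd <- .dedupe(lk)
  .RegulatoryLinks(dd$links, stats = list(duplicates = dd$duplicates))
}

#' Write a regulatory link table to TSV
#'
#' Writes 4 columns (source, interaction word, target, evidence) readable
#' back by [loadInteractions()]: the round trip reproduces the same link
#' multiset.
#'
#' @param x a \linkS4class{RegulatoryLinks} object
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeInteractions <- function(x, path) {
  stopifnot(is(x, "RegulatoryLinks"))
  lk <- x@links
  word <- c("represses", "regulates", "activates")[lk$sign + 2L]
  out <- data.frame(lk$source, word, lk$target, lk$evidence)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
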