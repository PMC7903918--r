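test_that("interaction tables are read, signed and deduplicated", {
  f <- writeTempTsv(c(
    "# curated links",
    "Hnf4a\tactivates\tGrp\tliterature",
    "Hnf4a\tactivates\tGrp\tliterature",
    "Trp53\trepresses\tFos\treporter assay"))
  x <- suppressMessages(loadInteractions(f))
  expect_s4_class(x, "RegulatoryLinks")
  expect_equal(length(x), 2L)
  lk <- interactions(x)
  expect_equal(lk[lk$source == "Hnf4a", "sign"], 1L)
  expect_equal(lk[lk$source == "Hnf4a", "target"], "Grp")
  expect_equal(lk[lk$source == "Trp53", "sign"], -1L)
  expect_equal(x@stats$duplicates, 1L)

  # dedupe is on (source, sign, target): evidence tags are ";"-joined
  f2 <- writeTempTsv(c("A\tactivates\tB\tdb1", "A\tactivates\tB\tdb2",
                       "A\trepresses\tB\tdb1"))
  x2 <- suppressMessages(loadInteractions(f2))
  expect_equal(length(x2), 2L)
  expect_equal(interactions(x2)$evidence[1L], "db1;db2")
})

test_that("interaction words map case-insensitively with sign-0 fallback", {
  f <- writeTempTsv(c("A\tUpregulates\tB", "C\tINHIBITS\tD",
                      "E\tregulates\tF", "G\tfrobnicates\tH"))
  expect_warning(x <- loadInteractions(f), "unknown word")
  lk <- interactions(x)
  expect_equal(setNames(lk$sign, lk$source),
               c(A = 1L, C = -1L, E = 0L, G = 0L))
})

test_that("degenerate and malformed interaction input is never silent", {
  empty <- writeTempTsv(character())
  expect_warning(x <- loadInteractions(empty), "no interaction")
  expect_equal(length(x), 0L)
  expect_error(loadInteractions(tempfile()), "not found")
  f <- writeTempTsv(c("A\tactivates\tB", "odd row", "C\trepresses"))
  expect_warning(x <- loadInteractions(f), "malformed")
  expect_equal(length(x), 1L)
  expect_equal(x@stats$skipped, 2L)
  # bookkeeping: kept + duplicates + skipped = rows read
  expect_equal(length(x) + x@stats$duplicates + x@stats$skipped,
               x@stats$rowsRead)
})

test_that("write/load round trip preserves the link multiset", {
  f <- writeTempTsv(c("A\tactivates\tB\tdb1", "B\trepresses\tC\tdb2",
                      "C\tregulates\tD\t", "Mir96\trepresses\tA\tseed-match"))
  x <- loadInteractions(f)
  out <- tempfile(fileext = ".tsv")
  writeInteractions(x, out)
  y <- loadInteractions(out)
  cols <- c("source", "sign", "target")
  expect_setequal(do.call(paste, interactions(x)[cols]),
                  do.call(paste, interactions(y)[cols]))
  expect_equal(length(x), length(y))
})

test_that("evidence filtering is a case-insensitive substring match", {
  f <- writeTempTsv(c("A\tactivates\tB\treporter assay",
                      "C\tactivates\tD\tmicroarray",
                      "E\trepresses\tF\tWestern blotting"))
  x <- loadInteractions(f)
  expect_equal(length(filterByEvidence(x, "reporter assay")), 1L)
  # case folding: "western" matches "Western blotting"
  kept <- filterByEvidence(x, "western")
  expect_equal(interactions(kept)$source, "E")
  expect_equal(tolower(interactions(kept)$evidence),
               tolower("Western blotting"))
  # allowing every class is the identity, order preserved
  all3 <- filterByEvidence(x, c("reporter", "microarray", "western"))
  expect_equal(interactions(all3), interactions(x))
  expect_error(filterByEvidence(x, character()), "non-empty")
  expect_equal(length(filterByEvidence(x, "luciferase")), 0L)
})

test_that("orthologue conversion renames one-to-one and drops ambiguous", {
  f <- writeTempTsv(c("TP53\trepresses\tFOS\tdb",
                      "MYC\tactivates\tFOS\tdb",
                      "Gata3\tactivates\tFOS\tdb"))
  x <- loadInteractions(f)
  map <- readOrthologueMap(writeTempTsv(c(
    "TP53\tTrp53", "FOS\tFos", "MYC\tMyca", "MYC\tMycb")))
  y <- mapOrthologues(x, map)
  lk <- interactions(y)
  # one-to-one endpoints renamed; ambiguous (MYC -> 2 IDs) dropped
  expect_setequal(lk$source, c("Trp53", "Gata3"))
  expect_true(all(lk$target == "Fos"))
  expect_equal(y@stats$orthologueDropped, 1L)
  # endpoints absent from the map pass through unchanged
  expect_true("Gata3" %in% lk$source)
  # no gene ID appears that is in neither the input nor the native side
  allowed <- c(interactions(x)$source, interactions(x)$target,
               unlist(map, use.names = FALSE))
  expect_true(all(c(lk$source, lk$target) %in% allowed))
})

test_that("renaming that makes links coincide re-deduplicates them", {
  f <- writeTempTsv(c("TP53\tactivates\tFos\tdbA", "Trp53\tactivates\tFos\tdbB"))
  x <- loadInteractions(f)
  y <- mapOrthologues(x, list(TP53 = "Trp53"))
  expect_equal(length(y), 1L)
  expect_equal(interactions(y)$evidence, "dbA;dbB")
})

test_that("upregulated genes with seed matches become miRNA targets", {
  mis <- data.frame(gene = c("Grp", "Ocm", "Tmc1"),
                    direction = c(1L, -1L, 1L))
  hits <- data.frame(gene = c("Grp", "Grp", "Ocm", "Tmc1"),
                     mirna = c("Mir96", "Mir183", "Mir96", "Mir96"),
                     count = c(2L, 1L, 3L, 0L))
  ed <- interactions(addMirnaTargetEdges(mis, hits))
  # one repressive edge per (miRNA, gene), regardless of match count;
  # downregulated or matchless genes yield nothing
  expect_equal(nrow(ed), 2L)
  expect_true(all(ed$sign == -1L))
  expect_setequal(paste(ed$source, ed$target),
                  c("Mir96 Grp", "Mir183 Grp"))
  expect_true(all(ed$evidence == "seed-match"))
})

test_that("misregulation tables parse directions and apply FDR cutoffs", {
  f <- writeTempTsv(c("Grp\tup\t2.1\t0.001", "Ocm\tdown\t-3\t0.01",
                      "Tmc1\t-1\t\t0.2", "Sema3e\t1.7\t1.7\t0.04"))
  m <- readMisregulation(f)
  expect_equal(setNames(m$direction, m$gene),
               c(Grp = 1L, Ocm = -1L, Tmc1 = -1L, Sema3e = 1L))
  m5 <- readMisregulation(f, fdrMax = 0.05)
  expect_setequal(m5$gene, c("Grp", "Ocm", "Sema3e"))
})
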