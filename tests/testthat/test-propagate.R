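chainEdges <- function() data.frame(
  source = c("Mir96", "A"), sign = c(-1L, -1L),
  target = c("A", "Slc26a5"), evidence = "", stringsAsFactors = FALSE)

test_that("path restriction keeps exactly the on-path nodes and edges", {
  ed <- data.frame(source = c("R", "A", "A"), sign = c(1L, 1L, 1L),
                   target = c("A", "G", "X"), evidence = "",
                   stringsAsFactors = FALSE)
  sub <- restrictToPaths(ed, roots = "R", targets = "G")
  # X has no onward path to a target: X and A->X removed
  expect_setequal(sub$nodes, c("R", "A", "G"))
  expect_equal(nrow(sub$edges), 2L)
  expect_false("X" %in% c(sub$edges$source, sub$edges$target))
  expect_equal(nrow(sub$excluded), 0L)
})

test_that("targets without upstream regulators are excluded, all-excluded is fatal", {
  ed <- data.frame(source = "R", sign = -1L, target = "G", evidence = "",
                   stringsAsFactors = FALSE)
  sub <- restrictToPaths(ed, roots = "R", targets = c("G", "Ccer2", "Rn7s1"))
  expect_setequal(sub$excluded$gene, c("Ccer2", "Rn7s1"))
  expect_true(all(sub$excluded$reason == "no_path"))
  expect_error(restrictToPaths(ed, roots = "R", targets = c("Ccer2", "Rn7s1")),
               "no target is reachable")
})

test_that("sign propagation walks a repression chain from a knockout root", {
  sub <- restrictToPaths(chainEdges(), "Mir96", "Slc26a5")
  st <- propagateScores(sub, c(Slc26a5 = -1L), "Mir96", "knockout")
  states <- setNames(st$direction, st$gene)
  # A represses Slc26a5 (down), so score(A) = (-1)*(-1) = +1: A is up
  expect_equal(states[["A"]], 1L)
  expect_equal(st$score[st$gene == "A"], 1L)
  expect_equal(st$status[st$gene == "A"], "predicted")
  # knockout root is down; the repressive root edge is then consistent
  expect_equal(states[["Mir96"]], -1L)
  expect_equal(st$status[st$gene == "Mir96"], "root")
  expect_equal(st$status[st$gene == "Slc26a5"], "observed")
  pr <- pruneInconsistent(sub, st)
  expect_equal(pr$removed, 0L)
})

test_that("balanced evidence yields a zero score and no prediction", {
  # U activates one up gene and represses another up gene: score 0
  ed <- data.frame(source = c("R", "U", "U"), sign = c(1L, 1L, -1L),
                   target = c("U", "G1", "G2"), evidence = "",
                   stringsAsFactors = FALSE)
  sub <- restrictToPaths(ed, "R", c("G1", "G2"))
  st <- propagateScores(sub, c(G1 = 1L, G2 = 1L), "R", "knockout")
  u <- st[st$gene == "U", ]
  expect_equal(u$score, 0L)
  expect_true(is.na(u$direction))
  expect_equal(u$status, "no_prediction")
})

test_that("propagation is odd: flipping observations and root flips predictions", {
  cs <- simulateCascade(nNodes = 120, noise = 0.2, seed = 41)
  sub <- restrictToPaths(cs$links, cs$root, cs$observed$gene)
  stKo <- propagateScores(sub, cs$observed, cs$root, "knockout")
  flipped <- transform(cs$observed, direction = -direction)
  stOe <- propagateScores(sub, flipped, cs$root, "overexpression")
  expect_equal(stOe$gene, stKo$gene)
  expect_equal(stOe$direction, -stKo$direction)
  expect_equal(stOe$score, -stKo$score)
  expect_equal(stOe$status, stKo$status)
  # and the retained edge set is unchanged
  prKo <- pruneInconsistent(sub, stKo)
  prOe <- pruneInconsistent(sub, stOe)
  expect_equal(prKo$edges[c("source", "sign", "target")],
               prOe$edges[c("source", "sign", "target")])
})

test_that("consistency decisions match the exhaustive sign truth table", {
  for (du in c(-1L, 1L)) for (s in c(-1L, 0L, 1L)) for (dv in c(-1L, 1L)) {
    ed <- data.frame(source = "u", sign = s, target = "v", evidence = "",
                     stringsAsFactors = FALSE)
    states <- data.frame(gene = c("u", "v"), direction = c(du, dv),
                         score = 0L, status = "observed",
                         stringsAsFactors = FALSE)
    pr <- pruneInconsistent(ed, states)
    shouldKeep <- s != 0L && du * s == dv
    expect_equal(nrow(pr$edges) == 1L, shouldKeep,
                 info = sprintf("du=%d s=%d dv=%d", du, s, dv))
    expect_equal(pr$removed, as.integer(!shouldKeep))
  }
  # an edge touching a no-prediction node is always removed
  ed <- data.frame(source = "u", sign = 1L, target = "v", evidence = "",
                   stringsAsFactors = FALSE)
  states <- data.frame(gene = c("u", "v"), direction = c(1L, NA_integer_),
                       score = c(1L, 0L),
                       status = c("predicted", "no_prediction"),
                       stringsAsFactors = FALSE)
  expect_equal(pruneInconsistent(ed, states)$removed, 1L)
})

test_that("shortest-path assembly keeps minimal paths and all ties", {
  # length-2 and length-3 consistent routes to the same target
  ed <- data.frame(
    source = c("R", "A", "R", "B", "C"), sign = 1L,
    target = c("A", "G", "B", "C", "G"), evidence = "",
    stringsAsFactors = FALSE)
  states <- data.frame(gene = c("R", "A", "B", "C", "G"),
                       direction = 1L, score = 1L,
                       status = c("root", rep("predicted", 3), "observed"),
                       stringsAsFactors = FALSE)
  net <- shortestPathNetwork(ed, states, "R", "G")
  expect_setequal(paste(networkEdges(net)$source, networkEdges(net)$target),
                  c("R A", "A G"))
  expect_equal(lengths(networkPaths(net)$G), 3L)  # one path of 3 nodes
  # two distinct length-2 paths: both retained
  ed2 <- data.frame(source = c("R", "A", "R", "B"), sign = 1L,
                    target = c("A", "G", "B", "G"), evidence = "",
                    stringsAsFactors = FALSE)
  net2 <- shortestPathNetwork(ed2, states, "R", "G")
  expect_equal(nrow(networkEdges(net2)), 4L)
  expect_equal(length(networkPaths(net2)$G), 2L)
})

test_that("shortest-path networks match exhaustive path enumeration", {
  withr::with_seed(23, {
    for (i in 1:40) {
      ed <- randomDigraph(sample(4:6, 1), pEdge = 0.35)
      if (!nrow(ed)) next
      nodes <- unique(c(ed$source, ed$target))
      root <- nodes[1L]; targets <- setdiff(nodes, root)
      oracle <- bruteShortestPathEdges(ed, root, targets)
      if (!length(oracle)) next
      states <- data.frame(gene = nodes, direction = 1L, score = 1L,
                           status = "predicted", stringsAsFactors = FALSE)
      net <- shortestPathNetwork(ed, states, root, targets)
      got <- sort(unique(paste(networkEdges(net)$source,
                               networkEdges(net)$target, sep = "->")))
      expect_equal(got, oracle)
    }
  })
})

test_that("each stage of the pipeline only ever shrinks the edge set", {
  cs <- simulateCascade(nNodes = 150, noise = 0.3, crossFrac = 0.5, seed = 59)
  edgeKey <- function(df) paste(df$source, df$sign, df$target)
  input <- interactions(cs$links)
  sub <- restrictToPaths(cs$links, cs$root, cs$observed$gene)
  st <- propagateScores(sub, cs$observed, cs$root, "knockout")
  pr <- pruneInconsistent(sub, st)
  net <- shortestPathNetwork(pr, st, cs$root, cs$observed$gene,
                             priorExcluded = sub$excluded)
  expect_true(all(edgeKey(sub$edges) %in% edgeKey(input)))
  expect_true(all(edgeKey(pr$edges) %in% edgeKey(sub$edges)))
  expect_true(all(edgeKey(networkEdges(net)) %in% edgeKey(pr$edges)))
  # every non-excluded target is reachable in the final network paths
  reached <- names(networkPaths(net))
  expect_setequal(c(reached, excludedTargets(net)$gene), cs$observed$gene)
})

test_that("the causal network pipeline is deterministic", {
  cs <- simulateCascade(nNodes = 80, noise = 0.1, seed = 3)
  n1 <- buildCausalNetwork(cs$links, cs$observed, cs$root, "knockout")
  n2 <- buildCausalNetwork(cs$links, cs$observed, cs$root, "knockout")
  expect_equal(networkNodes(n1), networkNodes(n2))
  expect_equal(networkEdges(n1), networkEdges(n2))
  expect_equal(networkPaths(n1), networkPaths(n2))
})

test_that("noise-free planted cascades are recovered perfectly", {
  cs <- simulateCascade(nNodes = 100, noise = 0, fractionObserved = 1,
                        seed = 88)
  sub <- restrictToPaths(cs$links, cs$root, cs$observed$gene)
  st <- propagateScores(sub, cs$observed, cs$root, "knockout")
  truth <- setNames(cs$truth$direction, cs$truth$gene)
  predicted <- st[st$status == "predicted", ]
  expect_gt(nrow(predicted), 0L)
  expect_equal(predicted$direction, unname(truth[predicted$gene]))
  expect_equal(pruneInconsistent(sub, st)$removed, 0L)
})

test_that("cycles hit the sweep cap and oscillating genes get no prediction", {
  # two-cycle with contradictory signs can never reach a fixed point
  ed <- data.frame(source = c("R", "A", "B", "A"), sign = c(1L, 1L, -1L, 1L),
                   target = c("A", "B", "A", "G"), evidence = "",
                   stringsAsFactors = FALSE)
  sub <- restrictToPaths(ed, "R", "G")
  expect_warning(
    st <- propagateScores(sub, c(G = 1L), "R", "knockout", maxIter = 10L),
    "did not converge")
  osc <- st[st$gene %in% c("A", "B"), ]
  expect_true(any(osc$status == "no_prediction"))
})

test_that("held-out genes are validated as correct/incorrect/no-prediction", {
  # planted cascade: held-out internal on the unique consistent path
  ed <- data.frame(
    source = c("R", "M", "M", "R", "U", "U"),
    sign   = c(-1L, 1L, 1L, 1L, 1L, -1L),
    target = c("M", "G1", "G2", "U", "G3", "G4"), evidence = "",
    stringsAsFactors = FALSE)
  obs <- c(G1 = 1L, G2 = 1L, M = 1L, G3 = 1L, G4 = 1L)
  v <- validateAgainstStudy(ed, obs, "R", "knockout",
                            heldOut = c(M = 1L, U = -1L))
  pg <- setNames(v$perGene$verdict, v$perGene$gene)
  expect_equal(pg[["M"]], "correct")        # score(M) = +2, known up
  expect_equal(pg[["U"]], "no_prediction")  # +1 - 1 = 0
  expect_equal(unname(v$summary),
               c(1L, 0L, 1L))
  # adversarial: invert the held-out gene's known sign
  v2 <- validateAgainstStudy(ed, obs, "R", "knockout",
                             heldOut = c(M = -1L))
  expect_equal(v2$perGene$verdict, "incorrect")
  # a held-out gene absent from the subnetwork yields no_prediction
  v3 <- validateAgainstStudy(ed, obs, "R", "knockout",
                             heldOut = c(Zzz = 1L))
  expect_equal(v3$perGene$verdict, "no_prediction")
  expect_equal(v3$perGene$reason, "absent_from_subnetwork")
})

test_that("SIF export writes Cytoscape-loadable edge and attribute files", {
  sub <- restrictToPaths(chainEdges(), "Mir96", "Slc26a5")
  st <- propagateScores(sub, c(Slc26a5 = -1L), "Mir96", "knockout")
  pr <- pruneInconsistent(sub, st)
  net <- shortestPathNetwork(pr, st, "Mir96", "Slc26a5")
  prefix <- tempfile()
  files <- writeSif(net, prefix)
  expect_true(all(file.exists(files)))
  sif <- read.delim(paste0(prefix, ".sif"), header = FALSE)
  expect_equal(ncol(sif), 3L)
  expect_true(all(sif$V2 %in% c("activates", "represses")))
  nodes <- read.delim(paste0(prefix, ".nodes.tsv"))
  expect_setequal(nodes$gene, c("Mir96", "A", "Slc26a5"))
})
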