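pathABC <- makeNet(data.frame(from = c("A", "B"), to = c("B", "C")))
star4 <- makeNet(data.frame(from = "c", to = c("l1", "l2", "l3", "l4")))
cycle4 <- makeNet(data.frame(from = c("a", "b", "c", "d"),
                             to = c("b", "c", "d", "a")))
k4 <- makeNet(data.frame(from = c("a", "a", "a", "b", "b", "c"),
                         to = c("b", "c", "d", "c", "d", "d")))

test_that("degree counts distinct neighbors on canonical graphs", {
  expect_equal(degreeCentrality(pathABC), c(A = 1L, B = 2L, C = 1L))
  expect_equal(unname(degreeCentrality(star4)["c"]), 4L)
  expect_true(all(degreeCentrality(k4) == 3L))
  empty <- pharmNetwork(data.frame(from = character(), to = character()),
                        stats::setNames(character(0), character(0)))
  expect_error(degreeCentrality(empty), "empty")
})

test_that("betweenness matches closed forms on path, star and cycle", {
  expect_equal(betweennessCentrality(pathABC), c(A = 0, B = 1, C = 0))
  # the star center mediates all C(4,2) = 6 leaf pairs
  expect_equal(unname(betweennessCentrality(star4)["c"]), 6)
  expect_true(all(betweennessCentrality(star4)[c("l1", "l2", "l3", "l4")] == 0))
  # on a 4-cycle each node carries half of its single opposite pair
  expect_equal(unname(betweennessCentrality(cycle4)), rep(0.5, 4))
})

test_that("closeness uses the component-scaled convention", {
  clo <- closenessCentrality(pathABC)
  expect_equal(unname(clo["B"]), 1)
  expect_equal(unname(clo["A"]), 2 / 3)
  # complete graph: all distances 1
  expect_true(all(abs(closenessCentrality(k4) - 1) < 1e-12))
  # isolated node is 0 by convention
  iso <- makeNet(data.frame(from = "a", to = "b"),
                 roles = c(a = "other_protein", b = "other_protein",
                           z = "other_protein"))
  expect_equal(unname(closenessCentrality(iso)["z"]), 0)
})

test_that("centralities agree with enumeration oracles on random connected graphs", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    edges <- randConnectedEdges(n, extra = sample(0:3, 1))
    net <- makeNet(edges)
    ids <- nodeIds(net)
    deg <- degreeCentrality(net)
    adj <- adjacencyList(edges, ids)
    expect_equal(unname(deg[ids]), unname(lengths(adj)[ids]))
    expect_lt(max(abs(betweennessCentrality(net)[ids] -
                        oracleBetweenness(edges, ids)[ids])), 1e-9)
    expect_lt(max(abs(closenessCentrality(net)[ids] -
                        oracleCloseness(edges, ids)[ids])), 1e-9)
  }
})

test_that("centralities handle disconnected graphs", {
  # two components: triangle + edge
  edges <- data.frame(from = c("a", "a", "b", "x"), to = c("b", "c", "c", "y"))
  net <- makeNet(edges)
  ids <- nodeIds(net)
  expect_equal(unname(betweennessCentrality(net)[ids]),
               unname(oracleBetweenness(edges, ids)[ids]))
  expect_equal(unname(closenessCentrality(net)[ids]),
               unname(oracleCloseness(edges, ids)[ids]), tolerance = 1e-12)
  expect_true(all(closenessCentrality(net) <= 1))
})

sixNode <- makeNet(data.frame(from = c("A", "A", "B", "C", "D", "E"),
                              to = c("B", "C", "C", "D", "E", "F")))

test_that("the three-index screen equals the brute-force intersection filter", {
  # vacuous screen keeps everything
  all_zero <- screeningThresholds(0, 0, 0, mode = "absolute")
  res <- screenNodes(sixNode, all_zero)
  expect_setequal(nodeIds(res$network), nodeIds(sixNode))

  # triangle {A,B,C} with pendant chain C-D-E-F under absolute cutoffs
  thr <- screeningThresholds(2, 1, 0.4, mode = "absolute")
  res <- screenNodes(sixNode, thr)
  tab <- centralityTable(sixNode)
  brute <- tab$node_id[tab$degree >= 2 & tab$betweenness >= 1 & tab$closeness >= 0.4]
  expect_setequal(nodeIds(res$network), brute)
  expect_equal(res$table$retained, tab$node_id %in% brute)

  # retained set is the intersection of the three single-index screens
  single <- function(d, b, c) tab$node_id[tab$degree >= d &
                                            tab$betweenness >= b &
                                            tab$closeness >= c]
  expect_setequal(nodeIds(res$network),
                  Reduce(intersect, list(single(2, 0, 0), single(0, 1, 0),
                                         single(0, 0, 0.4))))

  expect_error(screenNodes(sixNode, screeningThresholds(99, 0, 0, "absolute")),
               "zero nodes")
})

test_that("quantile screening equals the brute-force median filter", {
  set.seed(22)
  for (rep in 1:10) {
    net <- makeNet(randConnectedEdges(12, extra = sample(0:4, 1)))
    tab <- centralityTable(net)
    res <- screenNodes(net, screeningThresholds())  # median on all three
    med <- function(x) quantile(x, 0.5, type = 1, names = FALSE)
    brute <- tab$node_id[tab$degree >= med(tab$degree) &
                           tab$betweenness >= med(tab$betweenness) &
                           tab$closeness >= med(tab$closeness)]
    expect_setequal(nodeIds(res$network), brute)
  }
})

test_that("median screening keeps every node of a complete graph (all indices tie)", {
  res <- screenNodes(k4, screeningThresholds())
  expect_setequal(nodeIds(res$network), nodeIds(k4))
})

test_that("raising any single threshold never grows the retained set", {
  set.seed(23)
  net <- makeNet(randConnectedEdges(12, extra = 4))
  tab <- centralityTable(net)
  for (rep in 1:25) {
    d <- runif(1, 0, 4); b <- runif(1, 0, 10); c <- runif(1, 0, 1)
    base <- tab$node_id[tab$degree >= d & tab$betweenness >= b & tab$closeness >= c]
    if (!length(base)) next
    raised <- list(c(d + 1, b, c), c(d, b + 2, c), c(d, b, c + 0.1))
    for (r in raised) {
      res <- tryCatch(
        screenNodes(net, screeningThresholds(r[1], r[2], r[3], "absolute"),
                    table = tab),
        error = function(e) NULL)  # zero retention is an allowed shrink
      kept <- if (is.null(res)) character(0) else nodeIds(res$network)
      expect_true(all(kept %in% base))
    }
  }
})

test_that("the two-stage screen recomputes centralities before the second pass", {
  # vacuous stages are idempotent
  zero <- screeningThresholds(0, 0, 0, "absolute")
  res <- twoStageScreen(sixNode, zero, stage2 = zero)
  expect_setequal(nodeIds(res$stage2$network), nodeIds(sixNode))

  # top-3 by degree among stage-1 survivors, lexicographic ties
  res <- twoStageScreen(sixNode, zero, topK = 3)
  tab <- centralityTable(sixNode)
  expected <- tab$node_id[order(-tab$degree, tab$node_id)][1:3]
  expect_setequal(nodeIds(res$stage2$network), expected)

  # sequential brute-force two-pass filter on a planted-hub fixture
  fx <- defaultFixture()
  net <- suppressMessages(buildPPINetwork(
    unique(fx@chemRecords$target_id[fx@chemRecords$score > 0.4]),
    fx@diseaseTargets,
    fx@ppiRecords[fx@ppiRecords$score > 0.7, , drop = FALSE]))
  res <- twoStageScreen(net, screeningThresholds(), stage2 = screeningThresholds())
  med <- function(x) quantile(x, 0.5, type = 1, names = FALSE)
  tab1 <- centralityTable(net)
  pass1 <- tab1$node_id[tab1$degree >= med(tab1$degree) &
                          tab1$betweenness >= med(tab1$betweenness) &
                          tab1$closeness >= med(tab1$closeness)]
  sub <- inducedSubnetwork(net, pass1)
  tab2 <- centralityTable(sub)
  pass2 <- tab2$node_id[tab2$degree >= med(tab2$degree) &
                          tab2$betweenness >= med(tab2$betweenness) &
                          tab2$closeness >= med(tab2$closeness)]
  expect_setequal(nodeIds(res$stage1$network), pass1)
  expect_setequal(nodeIds(res$stage2$network), pass2)

  expect_error(twoStageScreen(sixNode, zero), "exactly one")
  expect_error(twoStageScreen(sixNode, zero, stage2 = zero, topK = 3), "exactly one")
})
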