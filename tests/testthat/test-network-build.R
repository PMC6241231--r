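herb_tab <- data.frame(
  herb_label = c("H1", "H1", "H2"),
  compound_id = c("c1", "c2", "c3"),
  compound_name = c("alpha", "beta", "gamma"),
  stringsAsFactors = FALSE)

recs <- function(src, tgt, score = 0.9) {
  data.frame(source_id = src, target_id = tgt,
             score = rep_len(score, length(src)),
             kind = rep_len("chemical-protein", length(src)),
             stringsAsFactors = FALSE)
}

test_that("the compound-target network is bipartite with one edge per record", {
  # two compounds hitting {T1,T2} and {T2}: 3 nodes, 3 edges
  net <- buildCompoundTargetNetwork(herb_tab, recs(c("c1", "c1", "c2"),
                                                  c("T1", "T2", "T2")))
  expect_equal(nodeCount(net), 4)  # c1, c2, T1, T2
  expect_equal(edgeCount(net), 3)
  expect_equal(sum(nodeRoles(net) == "compound"), 2)
  expect_equal(sum(nodeRoles(net) == "compound_target"), 2)

  # minimal bipartite case
  net <- buildCompoundTargetNetwork(herb_tab, recs("c1", "T1"))
  expect_equal(nodeCount(net), 2)
  expect_equal(edgeCount(net), 1)

  # unknown compounds are skipped with a logged count
  expect_message(
    net <- buildCompoundTargetNetwork(herb_tab, recs(c("c1", "zz"), c("T1", "T2"))),
    "skipped 1")
  expect_false("T2" %in% nodeIds(net))

  expect_error(buildCompoundTargetNetwork(herb_tab, recs(character(), character())),
               "nothing to build")
})

test_that("the herb-target-disease network links herbs to distinct targets with overlap roles", {
  # herb H1 hits {T1,T2}; disease set {T2,T3}: T3 is dropped, T2 is overlap
  net <- buildHerbTargetDiseaseNetwork(herb_tab,
                                       recs(c("c1", "c2"), c("T1", "T2")),
                                       c("T2", "T3"))
  expect_setequal(nodeIds(net), c("H1", "T1", "T2"))
  expect_equal(edgeCount(net), 2)
  expect_equal(unname(nodeRoles(net)[c("T1", "T2")]),
               c("compound_target", "compound_disease_target"))

  # two herbs sharing a single target
  net <- buildHerbTargetDiseaseNetwork(herb_tab,
                                       recs(c("c1", "c3"), c("T1", "T1")),
                                       "XX")
  expect_equal(nodeCount(net), 3)
  expect_equal(edgeCount(net), 2)

  # per-herb degree equals its distinct-target count (duplicate compound hits collapse)
  net <- buildHerbTargetDiseaseNetwork(herb_tab,
                                       recs(c("c1", "c2", "c2"), c("T1", "T1", "T2")),
                                       "XX")
  expect_equal(unname(degreeCentrality(net)["H1"]), 2L)

  # disjoint disease set yields zero overlap roles
  expect_false(any(nodeRoles(net) == "compound_disease_target"))
  expect_error(buildHerbTargetDiseaseNetwork(herb_tab, recs("c1", "T1"),
                                             character(0)),
               "empty")
})

ppi <- function(a, b, score = 0.9) {
  data.frame(source_id = pmin(a, b), target_id = pmax(a, b), score = score,
             kind = "protein-protein", stringsAsFactors = FALSE)
}

test_that("the PPI network expands seeds by exactly one neighbor shell", {
  # D is only a neighbor of the non-seed C, so it is excluded
  net <- buildPPINetwork(c("A", "B"), character(0),
                         ppi(c("A", "B", "C"), c("C", "C", "D")))
  expect_setequal(nodeIds(net), c("A", "B", "C"))
  expect_equal(edgeCount(net), 2)
  expect_equal(unname(nodeRoles(net)["C"]), "other_protein")

  # neighbor-neighbor edges inside the shell are retained
  net <- buildPPINetwork("A", character(0),
                         ppi(c("A", "B", "A"), c("B", "C", "C")))
  expect_equal(nodeCount(net), 3)
  expect_equal(edgeCount(net), 3)

  # seeds in both sets get the overlap role; single-set seeds keep theirs
  net <- buildPPINetwork(c("A", "B"), c("B", "Z"),
                         ppi(c("A", "B"), c("B", "Z")))
  expect_equal(unname(nodeRoles(net)[c("A", "B", "Z")]),
               c("compound_target", "compound_disease_target", "disease_target"))

  # a seed with no incident PPI edge cannot anchor a network
  expect_message(
    expect_error(buildPPINetwork("Q", character(0), ppi("A", "B")),
                 "no seeds mapped"),
    "absent")
  expect_error(buildPPINetwork(character(0), character(0), ppi("A", "B")),
               "empty")
})

test_that("network summaries are consistent with role partitions", {
  net <- buildPPINetwork(c("A", "B"), character(0),
                         ppi(c("A", "B", "C"), c("C", "C", "D")))
  s <- networkSummary(net)
  expect_equal(s@nodeCount, 3L)
  expect_equal(s@edgeCount, 2L)
  expect_equal(sum(s@nodesByRole), s@nodeCount)
  expect_equal(unname(s@nodesByRole["compound_target"]), 2L)

  empty <- pharmNetwork(data.frame(from = character(), to = character()),
                        stats::setNames(character(0), character(0)))
  es <- networkSummary(empty)
  expect_equal(es@nodeCount, 0L)
  expect_equal(es@edgeCount, 0L)
})

test_that("role partition and self-loop/duplicate invariants hold on random fixtures", {
  set.seed(11)
  for (rep in 1:20) {
    universe <- sprintf("G%02d", 1:30)
    ct <- sample(universe, 8)
    dt <- sample(universe, 8)
    edges <- randConnectedEdges(30, extra = 15)
    edges$from <- universe[as.integer(sub("N", "", edges$from))]
    edges$to <- universe[as.integer(sub("N", "", edges$to))]
    rec <- data.frame(source_id = pmin(edges$from, edges$to),
                      target_id = pmax(edges$from, edges$to),
                      score = 0.9, kind = "protein-protein",
                      stringsAsFactors = FALSE)
    net <- suppressMessages(buildPPINetwork(ct, dt, rec))
    roles <- nodeRoles(net)
    # brute-force set algebra on the same seeds
    expect_setequal(names(roles)[roles == "compound_disease_target"],
                    intersect(intersect(ct, dt), names(roles)))
    expect_setequal(names(roles)[roles == "compound_target"],
                    intersect(setdiff(ct, dt), names(roles)))
    g <- asIgraph(net)
    expect_false(any(igraph::which_loop(g)))
    expect_false(any(igraph::which_multiple(g)))
    et <- edgeTable(net)
    expect_true(all(c(et$from, et$to) %in% nodeIds(net)))
  }
})

test_that("adding a PPI record never removes a node from the seeded network", {
  set.seed(12)
  for (rep in 1:10) {
    edges <- randConnectedEdges(15, extra = 5)
    rec <- data.frame(source_id = pmin(edges$from, edges$to),
                      target_id = pmax(edges$from, edges$to),
                      score = 0.9, kind = "protein-protein",
                      stringsAsFactors = FALSE)
    seeds <- sample(unique(c(rec$source_id, rec$target_id)), 3)
    base <- suppressMessages(buildPPINetwork(seeds, character(0), rec))
    extra <- rbind(rec, data.frame(source_id = "ZZA", target_id = seeds[1],
                                   score = 0.9, kind = "protein-protein"))
    grown <- suppressMessages(buildPPINetwork(seeds, character(0), extra))
    expect_true(all(nodeIds(base) %in% nodeIds(grown)))
  }
})
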