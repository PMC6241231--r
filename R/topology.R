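.edgeIndex <- function(network) {
  g <- network@graph
  n <- igraph::vcount(g)
  if (n == 0) stop("empty network")
  el <- igraph::as_edgelist(g, names = FALSE)
  list(n = n, ids = igraph::vertex_attr(g, "name"),
       from = as.integer(el[, 1]) - 1L, to = as.integer(el[, 2]) - 1L)
}

#' Degree centrality
#'
#' Number of distinct neighbors of each node (the graph is simple, so
#' this equals the incident-edge count).
#'
#' @param network a non-empty [PharmNetwork-class].
#' @return named integer vector over all nodes.
#' @export
degreeCentrality <- function(network) {
  ei <- .edgeIndex(network)
  deg <- tabulate(c(ei$from, ei$to) + 1L, nbins = ei$n)
  stats::setNames(as.integer(deg), ei$ids)
}

#' Betweenness centrality (raw pair-count scale)
#'
#' For every unordered node pair (s, t), a node v distinct from both
#' accumulates the fraction of shortest s-t paths passing through v.
#' Computed by Brandes' dependency-accumulation algorithm on the
#' unweighted, undirected graph; values are left unnormalized, matching
#' the convention of Cytoscape-style raw betweenness cutoffs.
#'
#' @param network a non-empty [PharmNetwork-class].
#' @return named numeric vector over all nodes.
#' @export
betweennessCentrality <- function(network) {
  ei <- .edgeIndex(network)
  stats::setNames(brandes_betweenness_cpp(ei$n, ei$from, ei$to), ei$ids)
}

#' Closeness centrality (component-scaled to [0,1])
#'
#' For node v with reachable set R(v) of size r (excluding v itself),
#' closeness is \code{(r / (n - 1)) * (r / sum of distances to R(v))}
#' (the Wasserman-Faust scaling), which is the plain inverse average
#' distance on connected graphs, penalizes small components, and is 0
#' for isolated nodes.
#'
#' @param network a non-empty [PharmNetwork-class].
#' @return named numeric vector over all nodes, each in [0,1].
#' @export
closenessCentrality <- function(network) {
  ei <- .edgeIndex(network)
  stats::setNames(closeness_wf_cpp(ei$n, ei$from, ei$to), ei$ids)
}

#' Full per-node centrality table
#'
#' @param network a non-empty [PharmNetwork-class].
#' @return data.frame with columns \code{node_id}, \code{role},
#'   \code{degree}, \code{betweenness}, \code{closeness}, in node-id
#'   order.
#' @export
centralityTable <- function(network) {
  deg <- degreeCentrality(network)
  btw <- betweennessCentrality(network)
  clo <- closenessCentrality(network)
  roles <- nodeRoles(network)
  ids <- sort(names(deg))
  data.frame(node_id = ids, role = unname(roles[ids]),
             degree = unname(deg[ids]), betweenness = unname(btw[ids]),
             closeness = unname(clo[ids]), stringsAsFactors = FALSE)
}

#' Construct screening thresholds
#'
#' @param degreeMin,betweennessMin,closenessMin cutoffs (absolute
#'   values, or quantile probabilities in quantile mode).
#' @param mode \code{"absolute"} or \code{"quantile"}. The default is
#'   the median of each index (quantile 0.5, lower interpolation).
#' @return a [ScreeningThresholds-class].
#' @export
screeningThresholds <- function(degreeMin = 0.5, betweennessMin = 0.5,
                                closenessMin = 0.5, mode = "quantile") {
  methods::new("ScreeningThresholds", degreeMin = as.numeric(degreeMin),
               betweennessMin = as.numeric(betweennessMin),
               closenessMin = as.numeric(closenessMin), mode = mode)
}

setMethod("show", "ScreeningThresholds", function(object) {
  cat(sprintf("ScreeningThresholds (%s): degree >= %g, betweenness >= %g, closeness >= %g\n",
              object@mode, object@degreeMin, object@betweennessMin,
              object@closenessMin))
  invisible(NULL)
})

.resolveCutoffs <- function(thresholds, table) {
  if (thresholds@mode == "absolute") {
    c(degree = thresholds@degreeMin, betweenness = thresholds@betweennessMin,
      closeness = thresholds@closenessMin)
  } else {
    # lower-interpolation (type 1) quantiles: deterministic on even n
    c(degree = stats::quantile(table$degree, thresholds@degreeMin, type = 1, names = FALSE),
      betweenness = stats::quantile(table$betweenness, thresholds@betweennessMin, type = 1, names = FALSE),
      closeness = stats::quantile(table$closeness, thresholds@closenessMin, type = 1, names = FALSE))
  }
}

#' Three-index node screen
#'
#' Retains every node whose degree, betweenness and closeness are all
#' at or above their cutoffs (inclusive comparisons). In quantile mode
#' each cutoff is the requested quantile of that index over all nodes
#' of \code{network}. Returns the induced subgraph on the retained
#' nodes together with the full centrality table for audit.
#'
#' @param network a non-empty [PharmNetwork-class].
#' @param thresholds a [ScreeningThresholds-class].
#' @param table optional precomputed [centralityTable()] of
#'   \code{network}; supply it to screen the same network repeatedly
#'   without recomputing centralities.
#' @return list with elements \code{network} (retained subnetwork),
#'   \code{table} (full centrality table with a logical
#'   \code{retained} column) and \code{cutoffs} (the absolute cutoffs
#'   applied).
#' @export
screenNodes <- function(network, thresholds, table = NULL) {
  stopifnot(methods::is(thresholds, "ScreeningThresholds"))
  if (is.null(table)) table <- centralityTable(network)
  cut <- .resolveCutoffs(thresholds, table)
  retained <- table$degree >= cut["degree"] &
    table$betweenness >= cut["betweenness"] &
    table$closeness >= cut["closeness"]
  if (!any(retained))
    stop("screen retained zero nodes; relax the thresholds")
  out <- table
  out$retained <- retained
  sub <- inducedSubnetwork(network, table$node_id[retained],
                           name = paste0(network@name, "_screened"))
  list(network = sub, table = out, cutoffs = cut)
}

#' Two-stage node screen
#'
#' Applies \code{stage1} to the full network, recomputes all three
#' centralities on the stage-1 induced subnetwork, then applies either
#' \code{stage2} thresholds or a fixed-size top-\code{topK}-by-degree
#' rule (ties broken lexicographically by node id) to obtain the core.
#'
#' @param network a non-empty [PharmNetwork-class].
#' @param stage1 a [ScreeningThresholds-class] for the first pass.
#' @param stage2 a [ScreeningThresholds-class] for the second pass, or
#'   \code{NULL} when \code{topK} is used.
#' @param topK integer: keep the \code{topK} highest-degree stage-1
#'   survivors (computed on the stage-1 subnetwork). Exactly one of
#'   \code{stage2} and \code{topK} must be supplied.
#' @return list with \code{stage1} and \code{stage2} elements, each a
#'   [screenNodes()]-style result; \code{stage2$network} is the core.
#' @export
twoStageScreen <- function(network, stage1, stage2 = NULL, topK = NULL) {
  if (is.null(stage2) == is.null(topK))
    stop("supply exactly one of stage2 thresholds or topK")
  s1 <- screenNodes(network, stage1)
  sub <- s1$network
  tab2 <- centralityTable(sub)
  if (!is.null(stage2)) {
    s2 <- screenNodes(sub, stage2, table = tab2)
  } else {
    topK <- as.integer(topK)
    if (topK < 1) stop("topK must be positive")
    o <- order(-tab2$degree, tab2$node_id)
    keep_ids <- tab2$node_id[o][seq_len(min(topK, nrow(tab2)))]
    out <- tab2
    out$retained <- tab2$node_id %in% keep_ids
    core <- inducedSubnetwork(sub, keep_ids, name = paste0(network@name, "_core"))
    s2 <- list(network = core, table = out, cutoffs = c(top_k = topK))
  }
  list(stage1 = s1, stage2 = s2)
}
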