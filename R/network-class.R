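#' Construct a typed interaction network
#'
#' Builds a [PharmNetwork-class] from an edge table and a role
#' assignment. Edges are undirected: each pair is canonicalized
#' (lexicographically smaller endpoint first), self-loops are removed
#' and duplicate pairs are collapsed keeping the maximum score. Nodes
#' and edges are stored in sorted order so construction is deterministic
#' regardless of input order.
#'
#' @param edges data.frame with columns \code{from}, \code{to} and
#'   optionally \code{score}. May have zero rows.
#' @param roles named character vector mapping every node id to one of
#'   the supported roles (\code{herb}, \code{compound},
#'   \code{compound_target}, \code{disease_target},
#'   \code{compound_disease_target}, \code{other_protein}). Nodes not
#'   appearing in \code{edges} are kept as isolated nodes.
#' @param name network name.
#' @return a [PharmNetwork-class] object.
#' @export
pharmNetwork <- function(edges, roles, name = "network") {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  if (is.null(names(roles)) || anyNA(names(roles)) || any(names(roles) == ""))
    stop("every role must be named by its node id")
  if (anyDuplicated(names(roles)))
    stop("duplicate node ids in role assignment")
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  score <- if ("score" %in% names(edges)) as.numeric(edges$score)[keep] else
    rep(NA_real_, length(from))
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(score, key, function(s) if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE))
    ord <- !duplicated(key)
    a <- a[ord]; b <- b[ord]; key <- key[ord]
    score <- as.numeric(agg[key])
  }
  o <- order(a, b)
  a <- a[o]; b <- b[o]; score <- score[o]
  missing_nodes <- setdiff(unique(c(a, b)), names(roles))
  if (length(missing_nodes))
    stop(sprintf("edge endpoint(s) without a role: %s",
                 paste(utils::head(missing_nodes, 5), collapse = ", ")))
  ids <- sort(names(roles))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids,
                            role = unname(roles[ids]))
  if (length(a)) {
    g <- igraph::add_edges(g, rbind(a, b))
    if (!all(is.na(score))) g <- igraph::set_edge_attr(g, "score", value = score)
  }
  methods::new("PharmNetwork", graph = g, name = name)
}

.asPharmNetwork <- function(g, name) {
  methods::new("PharmNetwork", graph = g, name = name)
}

#' Accessors for PharmNetwork objects
#'
#' \code{nodeIds} returns the sorted node identifiers; \code{nodeRoles}
#' a named character vector of roles; \code{edgeTable} a data.frame of
#' canonicalized edges (\code{from}, \code{to}, \code{score});
#' \code{asIgraph} the underlying \pkg{igraph} object.
#'
#' @param x a [PharmNetwork-class].
#' @return see each accessor's description.
#' @name PharmNetwork-accessors
NULL

#' @rdname PharmNetwork-accessors
#' @export
setMethod("nodeIds", "PharmNetwork", function(x)
  igraph::vertex_attr(x@graph, "name"))

#' @rdname PharmNetwork-accessors
#' @export
setMethod("nodeRoles", "PharmNetwork", function(x) {
  r <- igraph::vertex_attr(x@graph, "role")
  names(r) <- igraph::vertex_attr(x@graph, "name")
  r
})

#' @rdname PharmNetwork-accessors
#' @export
setMethod("nodeCount", "PharmNetwork", function(x) igraph::vcount(x@graph))

#' @rdname PharmNetwork-accessors
#' @export
setMethod("edgeCount", "PharmNetwork", function(x) igraph::ecount(x@graph))

#' @rdname PharmNetwork-accessors
#' @export
setMethod("edgeTable", "PharmNetwork", function(x) {
  if (igraph::ecount(x@graph) == 0)
    return(data.frame(from = character(), to = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(x@graph, names = TRUE)
  score <- igraph::edge_attr(x@graph, "score")
  if (is.null(score)) score <- rep(NA_real_, nrow(el))
  from <- pmin(el[, 1], el[, 2])
  to <- pmax(el[, 1], el[, 2])
  o <- order(from, to)
  data.frame(from = from[o], to = to[o], score = score[o],
             stringsAsFactors = FALSE)
})

#' @rdname PharmNetwork-accessors
#' @export
setMethod("asIgraph", "PharmNetwork", function(x) x@graph)

#' @rdname PharmNetwork-accessors
#' @export
setMethod("networkName", "PharmNetwork", function(x) x@name)

setMethod("show", "PharmNetwork", function(object) {
  cat(sprintf("PharmNetwork '%s': %d nodes, %d edges\n",
              object@name, igraph::vcount(object@graph),
              igraph::ecount(object@graph)))
  if (igraph::vcount(object@graph) > 0) {
    tab <- table(igraph::vertex_attr(object@graph, "role"))
    cat("  roles:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(NULL)
})

#' Induced subgraph on a node subset
#'
#' @param x a [PharmNetwork-class].
#' @param ids character vector of node ids to keep (must all exist).
#' @param name name for the subnetwork.
#' @return a [PharmNetwork-class] on \code{ids} with all edges of
#'   \code{x} whose both endpoints are kept.
#' @export
inducedSubnetwork <- function(x, ids, name = paste0(x@name, "_sub")) {
  stopifnot(methods::is(x, "PharmNetwork"))
  unknown <- setdiff(ids, nodeIds(x))
  if (length(unknown))
    stop(sprintf("unknown node id(s): %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  g <- igraph::induced_subgraph(x@graph, vids = ids)
  roles <- igraph::vertex_attr(g, "role")
  names(roles) <- igraph::vertex_attr(g, "name")
  et <- if (igraph::ecount(g)) {
    el <- igraph::as_edgelist(g, names = TRUE)
    sc <- igraph::edge_attr(g, "score")
    data.frame(from = el[, 1], to = el[, 2],
               score = if (is.null(sc)) NA_real_ else sc,
               stringsAsFactors = FALSE)
  } else data.frame(from = character(), to = character())
  pharmNetwork(et, roles, name = name)
}

#' Summarize a network's size and role composition
#'
#' @param x a [PharmNetwork-class].
#' @return a [NetworkSummary-class]: node count, edge count, and node
#'   counts per role (roles not present are omitted).
#' @rdname networkSummary
#' @export
setMethod("networkSummary", "PharmNetwork", function(x) {
  roles <- nodeRoles(x)
  byrole <- if (length(roles)) {
    tab <- table(roles)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(0), character(0))
  methods::new("NetworkSummary", name = x@name,
               nodeCount = as.integer(nodeCount(x)),
               edgeCount = as.integer(edgeCount(x)),
               nodesByRole = byrole)
})

setMethod("show", "NetworkSummary", function(object) {
  cat(sprintf("NetworkSummary '%s': %d nodes, %d edges\n",
              object@name, object@nodeCount, object@edgeCount))
  if (length(object@nodesByRole))
    cat("  ", paste(sprintf("%s=%d", names(object@nodesByRole),
                            object@nodesByRole), collapse = ", "), "\n")
  invisible(NULL)
})
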