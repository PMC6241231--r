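#' Write a network to a Cytoscape-consumable format
#'
#' Supported formats: \code{"sif"} (simple interaction format, one
#' \code{A TAB pp TAB B} line per edge, isolated nodes as single-field
#' lines, plus a sidecar node-attribute TSV so roles survive the round
#' trip), \code{"graphml"}, and \code{"tsv"} (edge table plus
#' node-attribute table). All outputs are written in sorted node/edge
#' order so identical networks yield byte-identical files.
#'
#' @param network a [PharmNetwork-class].
#' @param path base path \emph{without} extension; the format-specific
#'   extensions are appended.
#' @param format one of \code{"sif"}, \code{"graphml"}, \code{"tsv"}.
#' @param centrality optional data.frame with a \code{node_id} column
#'   and additional per-node columns (e.g. degree, betweenness,
#'   closeness) merged into the node-attribute table.
#' @return invisibly, the paths of the files written.
#' @seealso [readNetwork()]
#' @export
writeNetwork <- function(network, path, format = c("sif", "graphml", "tsv"),
                         centrality = NULL) {
  stopifnot(methods::is(network, "PharmNetwork"))
  if (length(format) == 1 && !format %in% c("sif", "graphml", "tsv"))
    stop(sprintf("unknown network format '%s' (use sif, graphml or tsv)", format))
  format <- match.arg(format)
  et <- edgeTable(network)
  files <- character(0)
  if (format == "sif") {
    sif_path <- paste0(path, ".sif")
    lines <- if (nrow(et)) paste(et$from, "pp", et$to, sep = "\t") else character(0)
    isolated <- setdiff(nodeIds(network), unique(c(et$from, et$to)))
    writeLines(c(lines, sort(isolated)), sif_path)
    files <- c(sif_path, .writeNodeTable(network, paste0(path, ".nodes.tsv"), centrality))
  } else if (format == "graphml") {
    gm_path <- paste0(path, ".graphml")
    igraph::write_graph(network@graph, gm_path, format = "graphml")
    files <- gm_path
  } else {
    edge_path <- paste0(path, ".edges.tsv")
    df <- et
    df$score <- ifelse(is.na(df$score), "", sprintf("%.6g", df$score))
    utils::write.table(df, edge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    files <- c(edge_path, .writeNodeTable(network, paste0(path, ".nodes.tsv"), centrality))
  }
  invisible(files)
}

.writeNodeTable <- function(network, path, centrality = NULL) {
  nd <- data.frame(id = nodeIds(network),
                   role = unname(nodeRoles(network)),
                   stringsAsFactors = FALSE)
  if (!is.null(centrality)) {
    stopifnot("node_id" %in% names(centrality))
    idx <- match(nd$id, centrality$node_id)
    for (col in setdiff(names(centrality), c("node_id", "role")))
      nd[[col]] <- centrality[[col]][idx]
  }
  nd <- nd[order(nd$id), , drop = FALSE]
  num <- vapply(nd, is.numeric, logical(1))
  for (col in names(nd)[num]) nd[[col]] <- sprintf("%.10g", nd[[col]])
  utils::write.table(nd, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

#' Read a network written by writeNetwork
#'
#' Reconstructs a [PharmNetwork-class] from any supported format; the
#' round trip is the identity on node set, edge set and role
#' assignment.
#'
#' @param path the base path passed to [writeNetwork()].
#' @param format one of \code{"sif"}, \code{"graphml"}, \code{"tsv"}.
#' @param name name for the reconstructed network.
#' @return a [PharmNetwork-class].
#' @export
readNetwork <- function(path, format = c("sif", "graphml", "tsv"),
                        name = "network") {
  if (length(format) == 1 && !format %in% c("sif", "graphml", "tsv"))
    stop(sprintf("unknown network format '%s' (use sif, graphml or tsv)", format))
  format <- match.arg(format)
  if (format == "sif") {
    sif_path <- paste0(path, ".sif")
    if (!file.exists(sif_path)) stop(sprintf("file not found: %s", sif_path))
    lines <- readLines(sif_path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    n_f <- lengths(fields)
    edges <- do.call(rbind, lapply(fields[n_f >= 3], function(f)
      data.frame(from = f[1], to = f[3], stringsAsFactors = FALSE)))
    if (is.null(edges)) edges <- data.frame(from = character(), to = character())
    singles <- vapply(fields[n_f == 1], `[`, character(1), 1L)
    roles <- .readNodeRoles(paste0(path, ".nodes.tsv"),
                            unique(c(edges$from, edges$to, singles)))
    pharmNetwork(edges, roles, name = name)
  } else if (format == "graphml") {
    gm_path <- paste0(path, ".graphml")
    if (!file.exists(gm_path)) stop(sprintf("file not found: %s", gm_path))
    g <- igraph::read_graph(gm_path, format = "graphml")
    roles <- igraph::vertex_attr(g, "role")
    names(roles) <- igraph::vertex_attr(g, "name")
    et <- if (igraph::ecount(g)) {
      el <- igraph::as_edgelist(g, names = TRUE)
      sc <- igraph::edge_attr(g, "score")
      if (!is.null(sc)) sc[is.nan(sc)] <- NA_real_
      data.frame(from = el[, 1], to = el[, 2],
                 score = if (is.null(sc)) NA_real_ else sc,
                 stringsAsFactors = FALSE)
    } else data.frame(from = character(), to = character())
    pharmNetwork(et, roles, name = name)
  } else {
    edge_path <- paste0(path, ".edges.tsv")
    if (!file.exists(edge_path)) stop(sprintf("file not found: %s", edge_path))
    et <- utils::read.delim(edge_path, stringsAsFactors = FALSE,
                            colClasses = c(from = "character", to = "character"))
    if (nrow(et) && is.character(et$score))
      et$score <- suppressWarnings(as.numeric(et$score))
    roles <- .readNodeRoles(paste0(path, ".nodes.tsv"),
                            unique(c(et$from, et$to)))
    pharmNetwork(et, roles, name = name)
  }
}

.readNodeRoles <- function(node_path, fallback_ids) {
  if (file.exists(node_path)) {
    nd <- utils::read.delim(node_path, stringsAsFactors = FALSE,
                            colClasses = "character")
    stats::setNames(nd$role, nd$id)
  } else {
    stats::setNames(rep("other_protein", length(fallback_ids)), fallback_ids)
  }
}

#' Write a centrality table as a Cytoscape node-attribute TSV
#'
#' @param table centrality data.frame (from [centralityTable()] or
#'   [screenNodes()]), written as-is with tab separation.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeCentralityTable <- function(table, path) {
  df <- table
  for (col in names(df)) if (is.numeric(df[[col]]))
    df[[col]] <- sprintf("%.10g", df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
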