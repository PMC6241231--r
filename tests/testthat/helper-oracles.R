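# Independent brute-force oracles and small graph builders used across
# the suite. These deliberately avoid the package's own algorithms: the
# betweenness oracle enumerates simple paths recursively, distances come
# from Floyd-Warshall, and the hypergeometric tail is summed from exact
# binomial coefficients.

makeNet <- function(edges, roles = NULL, name = "test") {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:2] <- c("from", "to")
  ids <- unique(c(edges$from, edges$to, names(roles)))
  full <- stats::setNames(rep("other_protein", length(ids)), ids)
  if (!is.null(roles)) full[names(roles)] <- roles
  pharmNetwork(edges, full, name = name)
}

# deterministic-ish random connected graph: a random recursive tree plus
# `extra` additional non-duplicate edges
randConnectedEdges <- function(n, extra = 0) {
  ids <- sprintf("N%02d", seq_len(n))
  from <- character(0); to <- character(0)
  for (i in 2:n) {
    j <- sample(seq_len(i - 1), 1)
    from <- c(from, ids[j]); to <- c(to, ids[i])
  }
  tries <- 0
  while (extra > 0 && tries < 100) {
    pair <- sort(sample(ids, 2))
    key <- paste(pmin(from, to), pmax(from, to))
    if (!(paste(pair[1], pair[2]) %in% key)) {
      from <- c(from, pair[1]); to <- c(to, pair[2])
      extra <- extra - 1
    }
    tries <- tries + 1
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

adjacencyList <- function(edges, ids) {
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (r in seq_len(nrow(edges))) {
    a <- edges$from[r]; b <- edges$to[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# all-pairs distances by Floyd-Warshall
oracleDistances <- function(edges, ids) {
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    d[edges$from[r], edges$to[r]] <- 1
    d[edges$to[r], edges$from[r]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# enumerate every shortest s-t path by depth-limited DFS over simple paths
enumShortestPaths <- function(adj, s, t, d) {
  paths <- list()
  rec <- function(path, v, depth) {
    if (v == t) {
      if (depth == d) paths[[length(paths) + 1]] <<- path
      return(invisible(NULL))
    }
    if (depth >= d) return(invisible(NULL))
    for (w in adj[[v]]) if (!(w %in% path)) rec(c(path, w), w, depth + 1)
  }
  rec(s, s, 0)
  paths
}

oracleBetweenness <- function(edges, ids) {
  adj <- adjacencyList(edges, ids)
  dmat <- oracleDistances(edges, ids)
  btw <- stats::setNames(rep(0, length(ids)), ids)
  n <- length(ids)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- ids[i]; t <- ids[j]
    if (!is.finite(dmat[s, t])) next
    paths <- enumShortestPaths(adj, s, t, dmat[s, t])
    sigma <- length(paths)
    if (sigma == 0) next
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      for (v in interior) btw[v] <- btw[v] + 1 / sigma
    }
  }
  btw
}

oracleCloseness <- function(edges, ids) {
  dmat <- oracleDistances(edges, ids)
  n <- length(ids)
  vapply(ids, function(v) {
    dv <- dmat[v, setdiff(ids, v)]
    reach <- dv[is.finite(dv)]
    r <- length(reach)
    if (r == 0 || n == 1) 0 else (r / (n - 1)) * (r / sum(reach))
  }, numeric(1))
}

# exact hypergeometric upper tail from binomial coefficients
exactHyperTail <- function(k, n, K, N) {
  if (k <= 0) return(1)
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

writeTempTSV <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

defaultFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateFixture(fixtureConfig(seed = 42))
    cache
  }
})

# run the full pipeline on a fixture written to disk; returns the
# runPipeline result plus the config used
runFixturePipeline <- function(fixture, out_dir = tempfile("pipe")) {
  in_dir <- tempfile("fixture")
  files <- fixtureToFiles(fixture, in_dir)
  cfg <- validateConfig(list(
    herb_table = files[["herb_table"]],
    chem_table = files[["chem_table"]],
    ppi_table = files[["ppi_table"]],
    disease_targets = files[["disease_targets"]],
    gene_sets = files[["gene_sets"]],
    id_mapping = files[["id_mapping"]],
    out_dir = out_dir))
  res <- suppressMessages(runPipeline(cfg))
  res$config <- cfg
  res$files <- files
  res
}
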