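#' @import methods
NULL

.NODE_ROLES <- c("herb", "compound", "compound_target", "disease_target",
                 "compound_disease_target", "other_protein")

#' Typed interaction network
#'
#' An undirected simple graph whose nodes carry a role label
#' (herb, compound, compound target, disease target, overlap target,
#' other protein). The graph itself is an \pkg{igraph} object; edge
#' confidence scores, where available, are carried as an edge attribute
#' and are never used as weights for topology.
#'
#' @slot graph an \code{igraph} object; vertices have \code{name} and
#'   \code{role} attributes, edges optionally a \code{score} attribute.
#' @slot name human-readable network name.
#'
#' @seealso [pharmNetwork()], [nodeRoles()], [networkSummary()]
#' @export
setClass("PharmNetwork", slots = c(graph = "ANY", name = "character"))

setValidity("PharmNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must be an igraph object")
  if (igraph::is_directed(g)) return("network must be undirected")
  if (any(igraph::which_loop(g))) return("network must not contain self-loops")
  if (any(igraph::which_multiple(g))) return("network must not contain duplicate edges")
  roles <- igraph::vertex_attr(g, "role")
  if (igraph::vcount(g) > 0) {
    if (is.null(roles) || anyNA(roles))
      return("every node must carry a role")
    bad <- setdiff(unique(roles), .NODE_ROLES)
    if (length(bad))
      return(sprintf("unknown node role(s): %s", paste(bad, collapse = ", ")))
    if (is.null(igraph::vertex_attr(g, "name")))
      return("every node must be named")
  }
  TRUE
})

#' Gene-set annotation collection
#'
#' A list of named gene sets (terms) over a background universe, as read
#' from a GMT file. The background size N defaults to the size of the
#' union of all member sets and can be overridden (e.g. with a genome
#' size) when a wider universe is intended.
#'
#' @slot termId character vector of term identifiers (unique).
#' @slot termName character vector of human-readable term names.
#' @slot members list of character vectors; uppercase, deduplicated
#'   member symbols per term.
#' @slot backgroundSize integer scalar, the universe size N.
#'
#' @seealso [readGeneSets()], [enrich()]
#' @export
setClass("AnnotationSet",
         slots = c(termId = "character", termName = "character",
                   members = "list", backgroundSize = "integer"))

setValidity("AnnotationSet", function(object) {
  if (length(object@termId) != length(object@termName) ||
      length(object@termId) != length(object@members))
    return("termId, termName and members must have equal length")
  if (anyDuplicated(object@termId)) return("term ids must be unique")
  sizes <- lengths(object@members)
  if (length(sizes) && any(sizes == 0)) return("every term must have at least one member")
  if (length(object@backgroundSize) != 1 || is.na(object@backgroundSize) ||
      object@backgroundSize < 1)
    return("backgroundSize must be a positive integer")
  if (length(sizes) && object@backgroundSize < max(sizes))
    return("backgroundSize must be at least the size of the largest term")
  TRUE
})

#' Per-index screening thresholds
#'
#' Cutoffs for the three-index node screen. In \code{absolute} mode the
#' three values are compared directly to each node's degree, betweenness
#' and closeness (inclusive, \code{>=}). In \code{quantile} mode each
#' value is a probability in [0,1] and the cutoff applied is that
#' quantile (lower interpolation) of the index's empirical distribution
#' over all nodes of the screened network.
#'
#' @slot degreeMin,betweennessMin,closenessMin numeric scalars.
#' @slot mode \code{"absolute"} or \code{"quantile"}.
#'
#' @seealso [screeningThresholds()], [screenNodes()]
#' @export
setClass("ScreeningThresholds",
         slots = c(degreeMin = "numeric", betweennessMin = "numeric",
                   closenessMin = "numeric", mode = "character"))

setValidity("ScreeningThresholds", function(object) {
  if (!object@mode %in% c("absolute", "quantile"))
    return("mode must be 'absolute' or 'quantile'")
  v <- c(object@degreeMin, object@betweennessMin, object@closenessMin)
  if (length(v) != 3 || anyNA(v)) return("all three cutoffs must be single non-NA numbers")
  if (object@mode == "quantile" && (any(v < 0) || any(v > 1)))
    return("in quantile mode all cutoffs must lie in [0,1]")
  TRUE
})

#' Synthetic fixture configuration
#'
#' Parameters of the synthetic data generator: how many herbs and
#' compounds, the sizes of the compound-target and disease-target sets
#' and their overlap, the preferential-attachment PPI layer, and the
#' annotation collection with one planted enriched term. Defaults
#' emulate a small herbal-formula study: 8 herbs carrying 5-12 active
#' compounds each, 120 compound targets, 60 disease targets sharing 8
#' symbols with them, a 600-node scale-free PPI layer (3 edges per new
#' node) with 10 planted hub seeds, and 30 gene sets of which one covers
#' 80\% of its members from the target sets.
#'
#' @seealso [fixtureConfig()], [generateFixture()]
#' @export
setClass("FixtureConfig",
         slots = c(nHerbs = "integer", compoundsPerHerb = "integer",
                   nTargets = "integer", nDiseaseTargets = "integer",
                   overlapTargets = "integer", ppiNodes = "integer",
                   ppiAttachEdges = "integer", nHubSeeds = "integer",
                   nTerms = "integer", plantedTermOverlap = "numeric",
                   seed = "integer"))

setValidity("FixtureConfig", function(object) {
  counts <- c(object@nHerbs, object@nTargets, object@nDiseaseTargets,
              object@ppiNodes, object@ppiAttachEdges, object@nHubSeeds,
              object@nTerms)
  if (anyNA(counts) || any(counts < 1)) return("all counts must be positive")
  if (length(object@compoundsPerHerb) != 2 || any(object@compoundsPerHerb < 1) ||
      object@compoundsPerHerb[1] > object@compoundsPerHerb[2])
    return("compoundsPerHerb must be an increasing positive range (lo, hi)")
  if (object@overlapTargets < 0 ||
      object@overlapTargets > min(object@nTargets, object@nDiseaseTargets))
    return("overlapTargets must be <= min(nTargets, nDiseaseTargets)")
  if (object@ppiAttachEdges >= object@ppiNodes)
    return("ppiAttachEdges must be smaller than ppiNodes")
  if (object@nTargets + object@nDiseaseTargets - object@overlapTargets >
      object@ppiNodes)
    return("target sets must fit inside the PPI node set")
  if (object@nHubSeeds > object@nTargets)
    return("nHubSeeds must not exceed nTargets")
  if (is.na(object@plantedTermOverlap) || object@plantedTermOverlap < 0 ||
      object@plantedTermOverlap > 1)
    return("plantedTermOverlap must lie in [0,1]")
  if (length(object@seed) != 1 || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})

#' Synthetic fixture
#'
#' A complete, internally consistent set of pipeline inputs plus the
#' ground truth planted into them (hub seed symbols, planted term id,
#' overlap target symbols).
#'
#' @slot herbTable data.frame (herb_label, compound_id, compound_name).
#' @slot chemRecords data.frame of chemical-protein interaction records.
#' @slot ppiRecords data.frame of protein-protein interaction records.
#' @slot diseaseTargets character vector of disease target symbols.
#' @slot annotations an [AnnotationSet-class].
#' @slot groundTruth list with \code{hub_seeds}, \code{planted_term},
#'   \code{overlap_targets}.
#' @slot config the [FixtureConfig-class] that produced the fixture.
#'
#' @seealso [generateFixture()], [fixtureToFiles()]
#' @export
setClass("Fixture",
         slots = c(herbTable = "data.frame", chemRecords = "data.frame",
                   ppiRecords = "data.frame", diseaseTargets = "character",
                   annotations = "AnnotationSet", groundTruth = "list",
                   config = "FixtureConfig"))

#' Network size summary
#'
#' Node and edge counts of a network together with the node count per
#' role.
#'
#' @slot name network name.
#' @slot nodeCount,edgeCount integer scalars.
#' @slot nodesByRole named integer vector (one entry per role present).
#'
#' @seealso [networkSummary()]
#' @export
setClass("NetworkSummary",
         slots = c(name = "character", nodeCount = "integer",
                   edgeCount = "integer", nodesByRole = "integer"))

setValidity("NetworkSummary", function(object) {
  if (object@nodeCount != sum(object@nodesByRole))
    return("nodeCount must equal the sum of nodesByRole")
  if (object@edgeCount < 0) return("edgeCount must be non-negative")
  TRUE
})
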