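#' Build the compound - compound-target bipartite network
#'
#' One node per active compound and per protein it interacts with, one
#' edge per surviving chemical-protein record. Records whose compound
#' is not listed in the herb-compound table are skipped with a logged
#' count; compounds left without any surviving record are excluded.
#'
#' @param herbTable herb-compound membership data.frame
#'   (\code{herb_label}, \code{compound_id}, \code{compound_name}).
#' @param chemRecords chemical-protein records from
#'   [readInteractionTable()] (already score-filtered and, if needed,
#'   identifier-mapped).
#' @return a [PharmNetwork-class] with roles \code{compound} and
#'   \code{compound_target}.
#' @export
buildCompoundTargetNetwork <- function(herbTable, chemRecords) {
  if (is.null(chemRecords) || nrow(chemRecords) == 0)
    stop("no chemical-protein records: nothing to build")
  known <- chemRecords$source_id %in% herbTable$compound_id
  if (any(!known))
    message(sprintf("buildCompoundTargetNetwork: skipped %d record(s) for %d unknown compound(s)",
                    sum(!known), length(unique(chemRecords$source_id[!known]))))
  rec <- chemRecords[known, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records left after dropping unknown compounds")
  compounds <- unique(rec$source_id)
  targets <- setdiff(unique(rec$target_id), compounds)
  roles <- c(stats::setNames(rep("compound", length(compounds)), compounds),
             stats::setNames(rep("compound_target", length(targets)), targets))
  pharmNetwork(data.frame(from = rec$source_id, to = rec$target_id,
                          score = rec$score, stringsAsFactors = FALSE),
               roles, name = "compound_target_network")
}

#' Build the herb - compound-target - disease-target network
#'
#' Links each herb to the distinct protein targets hit by any of its
#' compounds. Targets also present in the disease-target set get role
#' \code{compound_disease_target}; disease targets never hit by a
#' compound do not appear (this network links herbs to targets). A
#' herb's degree therefore equals its distinct-target count.
#'
#' @param herbTable herb-compound membership data.frame.
#' @param chemRecords chemical-protein records (score-filtered).
#' @param diseaseTargets character vector of disease target symbols.
#' @return a [PharmNetwork-class] with roles \code{herb},
#'   \code{compound_target} and \code{compound_disease_target}.
#' @export
buildHerbTargetDiseaseNetwork <- function(herbTable, chemRecords, diseaseTargets) {
  if (length(diseaseTargets) == 0) stop("disease target set is empty")
  if (is.null(chemRecords) || nrow(chemRecords) == 0)
    stop("no chemical-protein records: nothing to build")
  diseaseTargets <- unique(toupper(diseaseTargets))
  idx <- match(chemRecords$source_id, herbTable$compound_id)
  known <- !is.na(idx)
  if (any(!known))
    message(sprintf("buildHerbTargetDiseaseNetwork: skipped %d record(s) for unknown compounds",
                    sum(!known)))
  herb <- herbTable$herb_label[idx[known]]
  target <- chemRecords$target_id[known]
  if (!length(herb)) stop("no records left after dropping unknown compounds")
  pairs <- unique(data.frame(from = herb, to = target, stringsAsFactors = FALSE))
  targets <- unique(pairs$to)
  herbs <- unique(pairs$from)
  t_role <- ifelse(targets %in% diseaseTargets,
                   "compound_disease_target", "compound_target")
  roles <- c(stats::setNames(rep("herb", length(herbs)), herbs),
             stats::setNames(t_role, targets))
  pharmNetwork(pairs, roles, name = "herb_target_disease_network")
}

#' Build the seeded protein-protein interaction network
#'
#' Starting from the compound-target and disease-target seed sets, the
#' node set is every seed present in the PPI table plus all first
#' neighbors of any seed; the edge set is every PPI edge with both
#' endpoints in that node set (neighbor-neighbor edges included, i.e.
#' the induced subgraph). Roles: seeds in both sets are
#' \code{compound_disease_target}, seeds in one set keep that set's
#' role, non-seed neighbors are \code{other_protein}. Seeds absent from
#' the PPI table are excluded with a logged count.
#'
#' @param compoundTargets character vector of compound-target symbols.
#' @param diseaseTargets character vector of disease-target symbols.
#' @param ppiRecords protein-protein records from
#'   [readInteractionTable()] (already confidence-thresholded).
#' @return a [PharmNetwork-class].
#' @export
buildPPINetwork <- function(compoundTargets, diseaseTargets, ppiRecords) {
  compoundTargets <- unique(toupper(compoundTargets))
  diseaseTargets <- unique(toupper(diseaseTargets))
  if (length(compoundTargets) == 0 && length(diseaseTargets) == 0)
    stop("both seed sets are empty")
  if (is.null(ppiRecords) || nrow(ppiRecords) == 0)
    stop("no protein-protein records")
  seeds <- union(compoundTargets, diseaseTargets)
  universe <- unique(c(ppiRecords$source_id, ppiRecords$target_id))
  present <- intersect(seeds, universe)
  if (length(present) < length(seeds))
    message(sprintf("buildPPINetwork: %d seed(s) absent from the PPI table excluded",
                    length(seeds) - length(present)))
  if (length(present) == 0) stop("no seeds mapped to the PPI table")
  touches_seed <- ppiRecords$source_id %in% present | ppiRecords$target_id %in% present
  neighbors <- unique(c(ppiRecords$source_id[touches_seed],
                        ppiRecords$target_id[touches_seed]))
  nodes <- union(present, neighbors)
  keep <- ppiRecords$source_id %in% nodes & ppiRecords$target_id %in% nodes
  rec <- ppiRecords[keep, , drop = FALSE]
  roles <- ifelse(nodes %in% compoundTargets & nodes %in% diseaseTargets,
                  "compound_disease_target",
                  ifelse(nodes %in% compoundTargets, "compound_target",
                         ifelse(nodes %in% diseaseTargets, "disease_target",
                                "other_protein")))
  names(roles) <- nodes
  pharmNetwork(data.frame(from = rec$source_id, to = rec$target_id,
                          score = rec$score, stringsAsFactors = FALSE),
               roles, name = "ppi_network")
}
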