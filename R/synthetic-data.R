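#' Create a synthetic fixture configuration
#'
#' Defaults describe the study shape the pipeline is designed for:
#' 8 herbs with 5-12 active compounds each, 120 compound-target
#' symbols, 60 disease targets of which 8 overlap the compound-target
#' set, a 600-node preferential-attachment PPI layer attaching 3 edges
#' per new node with the 10 top-degree nodes planted as compound-target
#' hubs, and 30 annotation terms of which one is planted to draw 80\%
#' of its members from the target sets.
#'
#' @param nHerbs number of herbs.
#' @param compoundsPerHerb integer range (lo, hi) of compounds per herb.
#' @param nTargets number of compound-target symbols.
#' @param nDiseaseTargets number of disease-target symbols.
#' @param overlapTargets symbols shared by both target sets.
#' @param ppiNodes PPI layer size.
#' @param ppiAttachEdges edges attached per new PPI node (the
#'   preferential-attachment m).
#' @param nHubSeeds top-degree PPI nodes labelled as compound targets.
#' @param nTerms annotation terms (one planted).
#' @param plantedTermOverlap fraction of the planted term's members
#'   drawn from the compound-target/disease-target union.
#' @param seed integer seed; all fixture randomness flows from it.
#' @return a [FixtureConfig-class].
#' @export
fixtureConfig <- function(nHerbs = 8, compoundsPerHerb = c(5, 12),
                          nTargets = 120, nDiseaseTargets = 60,
                          overlapTargets = 8, ppiNodes = 600,
                          ppiAttachEdges = 3, nHubSeeds = 10,
                          nTerms = 30, plantedTermOverlap = 0.8,
                          seed = 42) {
  methods::new("FixtureConfig",
               nHerbs = as.integer(nHerbs),
               compoundsPerHerb = as.integer(compoundsPerHerb),
               nTargets = as.integer(nTargets),
               nDiseaseTargets = as.integer(nDiseaseTargets),
               overlapTargets = as.integer(overlapTargets),
               ppiNodes = as.integer(ppiNodes),
               ppiAttachEdges = as.integer(ppiAttachEdges),
               nHubSeeds = as.integer(nHubSeeds),
               nTerms = as.integer(nTerms),
               plantedTermOverlap = as.numeric(plantedTermOverlap),
               seed = as.integer(seed))
}

setMethod("show", "FixtureConfig", function(object) {
  cat(sprintf(paste0("FixtureConfig: %d herbs (%d-%d compounds), ",
                     "%d compound targets, %d disease targets (%d overlap), ",
                     "PPI %d nodes (m=%d, %d hub seeds), %d terms, seed %d\n"),
              object@nHerbs, object@compoundsPerHerb[1], object@compoundsPerHerb[2],
              object@nTargets, object@nDiseaseTargets, object@overlapTargets,
              object@ppiNodes, object@ppiAttachEdges, object@nHubSeeds,
              object@nTerms, object@seed))
  invisible(NULL)
})

# run code under a seed without disturbing the caller's random state
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# preferential attachment: nodes 1..n; the first m nodes start edgeless,
# each later node attaches m edges to distinct earlier nodes with
# probability proportional to (degree + 1). Exactly m * (n - m) edges.
.baEdges <- function(n, m) {
  deg <- integer(n)
  from <- integer(m * (n - m))
  to <- integer(m * (n - m))
  e <- 0L
  for (i in (m + 1L):n) {
    prev <- seq_len(i - 1L)
    targets <- if (length(prev) == m) prev else
      sample(prev, m, prob = deg[prev] + 1)
    for (t in targets) {
      e <- e + 1L
      from[e] <- i; to[e] <- t
      deg[t] <- deg[t] + 1L
    }
    deg[i] <- deg[i] + m
  }
  data.frame(from = from, to = to)
}

#' Generate a complete synthetic fixture
#'
#' Produces internally consistent pipeline inputs with known planted
#' structure: a herb-compound table, chemical-protein records whose
#' scores lie on a 1/1000 grid over [0.2, 1.0] (so the 0.4 confidence
#' cutoff bites), a preferential-attachment PPI layer with scores on
#' [0.5, 1.0] (so the 0.7 cutoff bites), a disease-target list
#' overlapping the compound-target set, and a GMT-style annotation
#' collection with one planted term whose in-target members are the
#' highest-degree target symbols. Deterministic given the config seed.
#'
#' @param config a [FixtureConfig-class].
#' @return a [Fixture-class] carrying the inputs and the ground truth
#'   (\code{hub_seeds}, \code{planted_term}, \code{overlap_targets}).
#' @export
generateFixture <- function(config = fixtureConfig()) {
  stopifnot(methods::is(config, "FixtureConfig"))
  methods::validObject(config)
  .withSeed(config@seed, {
    ## herbs and compounds
    herbs <- sprintf("HB%02d", seq_len(config@nHerbs))
    n_comp <- sample(seq(config@compoundsPerHerb[1], config@compoundsPerHerb[2]),
                     config@nHerbs, replace = TRUE)
    total_comp <- sum(n_comp)
    comp_ids <- sprintf("CP%04d", seq_len(total_comp))
    herbTable <- data.frame(herb_label = rep(herbs, n_comp),
                            compound_id = comp_ids,
                            compound_name = paste0("compound_", tolower(comp_ids)),
                            stringsAsFactors = FALSE)

    ## PPI layer by preferential attachment
    ba <- .baEdges(config@ppiNodes, config@ppiAttachEdges)
    deg <- tabulate(c(ba$from, ba$to), nbins = config@ppiNodes)

    ## symbol assignment: hubs first, then the remaining seeds at random
    ct_syms <- sprintf("CT%03d", seq_len(config@nTargets))
    overlap <- if (config@overlapTargets > 0)
      sample(ct_syms, config@overlapTargets) else character(0)
    n_dt_only <- config@nDiseaseTargets - config@overlapTargets
    dt_syms <- if (n_dt_only > 0) sprintf("DT%03d", seq_len(n_dt_only)) else character(0)
    disease <- sort(c(overlap, dt_syms))

    node_sym <- character(config@ppiNodes)
    ord <- order(-deg, seq_len(config@ppiNodes))
    hub_nodes <- ord[seq_len(config@nHubSeeds)]
    node_sym[hub_nodes] <- ct_syms[seq_len(config@nHubSeeds)]
    rest_seeds <- c(ct_syms[-seq_len(config@nHubSeeds)], dt_syms)
    free <- setdiff(seq_len(config@ppiNodes), hub_nodes)
    placed <- sample(free, length(rest_seeds))
    node_sym[placed] <- rest_seeds
    other <- setdiff(free, placed)
    node_sym[other] <- sprintf("PX%04d", seq_along(other))

    ppi_from <- node_sym[ba$from]
    ppi_to <- node_sym[ba$to]
    a <- pmin(ppi_from, ppi_to); b <- pmax(ppi_from, ppi_to)
    ppi_score <- sample(500:1000, nrow(ba), replace = TRUE) / 1000
    o <- order(a, b)
    ppiRecords <- data.frame(source_id = a[o], target_id = b[o],
                             score = ppi_score[o], kind = "protein-protein",
                             stringsAsFactors = FALSE)

    ## chemical-protein layer: every target covered once (round robin),
    ## plus 0-4 extra targets per compound
    pair_comp <- comp_ids[((seq_len(config@nTargets) - 1L) %% total_comp) + 1L]
    pairs <- data.frame(source_id = pair_comp, target_id = ct_syms,
                        stringsAsFactors = FALSE)
    extra <- lapply(seq_len(total_comp), function(i) {
      n_extra <- sample(0:4, 1)
      if (n_extra == 0) return(NULL)
      data.frame(source_id = comp_ids[i],
                 target_id = sample(ct_syms, n_extra),
                 stringsAsFactors = FALSE)
    })
    pairs <- rbind(pairs, do.call(rbind, extra))
    pairs <- pairs[!duplicated(pairs[, c("source_id", "target_id")]), , drop = FALSE]
    chem_score <- sample(200:1000, nrow(pairs), replace = TRUE) / 1000
    o <- order(pairs$source_id, pairs$target_id)
    chemRecords <- data.frame(source_id = pairs$source_id[o],
                              target_id = pairs$target_id[o],
                              score = chem_score[o], kind = "chemical-protein",
                              stringsAsFactors = FALSE)

    ## annotations: one planted term whose in-target members are the
    ## top-degree seed symbols, the rest uniform over all symbols
    planted_size <- 20L
    seed_set <- union(ct_syms, disease)
    n_in <- round(config@plantedTermOverlap * planted_size)
    seed_by_deg <- node_sym[ord][node_sym[ord] %in% seed_set]
    members_in <- seed_by_deg[seq_len(n_in)]
    non_seed <- setdiff(node_sym, seed_set)
    members_out <- if (planted_size - n_in > 0)
      sample(non_seed, planted_size - n_in) else character(0)
    planted_members <- sort(c(members_in, members_out))
    other_sizes <- sample(10:40, config@nTerms - 1L, replace = TRUE)
    other_members <- lapply(other_sizes, function(s) sort(sample(node_sym, s)))
    members <- c(list(planted_members), other_members)
    termId <- sprintf("TERM%03d", seq_len(config@nTerms))
    termName <- c("planted_process",
                  sprintf("random_process_%03d", seq_len(config@nTerms - 1L)))
    annotations <- methods::new("AnnotationSet", termId = termId,
                                termName = termName, members = members,
                                backgroundSize = length(unique(unlist(members))))

    methods::new("Fixture",
                 herbTable = herbTable, chemRecords = chemRecords,
                 ppiRecords = ppiRecords, diseaseTargets = disease,
                 annotations = annotations,
                 groundTruth = list(hub_seeds = node_sym[hub_nodes],
                                    planted_term = termId[1],
                                    overlap_targets = sort(overlap)),
                 config = config)
  })
}

setMethod("show", "Fixture", function(object) {
  cat(sprintf(paste0("Fixture: %d herbs / %d compounds, %d chem-protein records, ",
                     "%d PPI records, %d disease targets, %d terms\n"),
              length(unique(object@herbTable$herb_label)),
              nrow(object@herbTable), nrow(object@chemRecords),
              nrow(object@ppiRecords), length(object@diseaseTargets),
              length(object@annotations@termId)))
  invisible(NULL)
})

#' Write a fixture to disk in the formats the readers consume
#'
#' Emits seven files: the herb-compound TSV, the chemical-protein and
#' protein-protein interaction TSVs (0-1000 integer score dialect), the
#' disease-target list, the GMT annotation file, an identity
#' identifier-mapping TSV over all protein symbols, and a ground-truth
#' manifest (key: value lines). Reading these back through the package
#' readers reproduces the in-memory fixture exactly.
#'
#' @param fixture a [Fixture-class].
#' @param directory output directory (created if needed).
#' @return named character vector of the seven file paths.
#' @export
fixtureToFiles <- function(fixture, directory) {
  stopifnot(methods::is(fixture, "Fixture"))
  if (!is.character(directory) || length(directory) != 1 || !nzchar(directory))
    stop("directory must be a non-empty path")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop(sprintf("cannot create directory: %s", directory))
  p <- function(f) file.path(directory, f)

  utils::write.table(fixture@herbTable, p("herb_compounds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  chem <- data.frame(chemical = fixture@chemRecords$source_id,
                     protein = fixture@chemRecords$target_id,
                     combined_score = as.integer(round(fixture@chemRecords$score * 1000)))
  utils::write.table(chem, p("chemical_protein.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  ppi <- data.frame(protein1 = fixture@ppiRecords$source_id,
                    protein2 = fixture@ppiRecords$target_id,
                    combined_score = as.integer(round(fixture@ppiRecords$score * 1000)))
  utils::write.table(ppi, p("ppi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  writeLines(fixture@diseaseTargets, p("disease_targets.txt"))
  gmt <- vapply(seq_along(fixture@annotations@termId), function(i)
    paste(c(fixture@annotations@termId[i], fixture@annotations@termName[i],
            fixture@annotations@members[[i]]), collapse = "\t"), character(1))
  writeLines(gmt, p("annotations.gmt"))
  syms <- sort(unique(c(fixture@ppiRecords$source_id, fixture@ppiRecords$target_id,
                        fixture@chemRecords$target_id, fixture@diseaseTargets)))
  utils::write.table(data.frame(raw_id = syms, symbol = syms),
                     p("id_mapping.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  gt <- fixture@groundTruth
  writeLines(c(sprintf("hub_seeds: %s", paste(gt$hub_seeds, collapse = ",")),
               sprintf("planted_term: %s", gt$planted_term),
               sprintf("overlap_targets: %s", paste(gt$overlap_targets, collapse = ","))),
             p("ground_truth.txt"))
  c(herb_table = p("herb_compounds.tsv"),
    chem_table = p("chemical_protein.tsv"),
    ppi_table = p("ppi.tsv"),
    disease_targets = p("disease_targets.txt"),
    gene_sets = p("annotations.gmt"),
    id_mapping = p("id_mapping.tsv"),
    ground_truth = p("ground_truth.txt"))
}
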