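.CONFIG_DEFAULTS <- list(
  herb_table = NULL,            # required paths
  chem_table = NULL,
  ppi_table = NULL,
  disease_targets = NULL,
  gene_sets = NULL,
  id_mapping = NULL,            # optional: identity pass-through when absent
  out_dir = NULL,               # required
  chem_score_threshold = 0.4,
  ppi_score_threshold = 0.7,
  screen_mode = "quantile",
  stage1_degree_min = 0.5,
  stage1_betweenness_min = 0.5,
  stage1_closeness_min = 0.5,
  stage2_top_k = 40,
  stage2_degree_min = NULL,     # set all three to use a thresholded stage 2
  stage2_betweenness_min = NULL,
  stage2_closeness_min = NULL,
  enrichment_min_hits = 2,
  enrichment_background = NULL,
  ease = FALSE,
  seed = 1
)

.REQUIRED_KEYS <- c("herb_table", "chem_table", "ppi_table",
                    "disease_targets", "gene_sets", "out_dir")

#' Validate and default a pipeline configuration
#'
#' Reads a flat key-value (YAML) configuration file, fills in every
#' documented default, range-checks thresholds and rejects unknown keys
#' (suggesting the nearest valid key, which catches typos).
#'
#' @param config path to a YAML file, or a named list of the same keys.
#' @return a fully defaulted configuration list (class
#'   \code{PipelineConfig}).
#' @export
validateConfig <- function(config) {
  user <- if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    yaml::read_yaml(config)
  } else if (is.list(config)) config else
    stop("config must be a file path or a named list")
  if (length(user) && (is.null(names(user)) || any(!nzchar(names(user)))))
    stop("config entries must all be named")
  unknown <- setdiff(names(user), names(.CONFIG_DEFAULTS))
  if (length(unknown)) {
    key <- unknown[1]
    d <- utils::adist(key, names(.CONFIG_DEFAULTS))
    stop(sprintf("unknown config key '%s'; did you mean '%s'?",
                 key, names(.CONFIG_DEFAULTS)[which.min(d)]))
  }
  cfg <- .CONFIG_DEFAULTS
  cfg[names(user)] <- user
  missing_req <- .REQUIRED_KEYS[vapply(cfg[.REQUIRED_KEYS], is.null, logical(1))]
  if (length(missing_req))
    stop(sprintf("missing required config key(s): %s",
                 paste(missing_req, collapse = ", ")))
  for (key in c("chem_score_threshold", "ppi_score_threshold")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop(sprintf("config key '%s' must lie in [0,1], got %s", key, format(v)))
  }
  if (!cfg$screen_mode %in% c("quantile", "absolute"))
    stop("config key 'screen_mode' must be 'quantile' or 'absolute'")
  if (cfg$screen_mode == "quantile") {
    for (key in c("stage1_degree_min", "stage1_betweenness_min", "stage1_closeness_min")) {
      v <- cfg[[key]]
      if (!is.numeric(v) || v < 0 || v > 1)
        stop(sprintf("config key '%s' must lie in [0,1] in quantile mode", key))
    }
  }
  stage2_thr <- c("stage2_degree_min", "stage2_betweenness_min", "stage2_closeness_min")
  n_set <- sum(!vapply(cfg[stage2_thr], is.null, logical(1)))
  if (n_set > 0 && n_set < 3)
    stop("set all three stage2_*_min keys or none")
  if (n_set == 0 && (!is.numeric(cfg$stage2_top_k) || cfg$stage2_top_k < 1))
    stop("config key 'stage2_top_k' must be a positive integer")
  if (!is.numeric(cfg$enrichment_min_hits) || cfg$enrichment_min_hits < 1)
    stop("config key 'enrichment_min_hits' must be at least 1")
  inputs <- unlist(cfg[c(.REQUIRED_KEYS[.REQUIRED_KEYS != "out_dir"], "id_mapping")])
  if (cfg$out_dir %in% inputs)
    stop("config key 'out_dir' must be distinct from the input paths")
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.countDataRows <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(0L)
  f <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- length(f) >= 3 && suppressWarnings(is.na(as.numeric(f[3])))
  length(lines) - as.integer(has_header)
}

#' Run the complete analysis pipeline
#'
#' Reads and filters the interaction tables, builds the three networks
#' (compound-target, herb-target-disease, seeded PPI), performs the
#' two-stage centrality screen on the PPI network, runs enrichment on
#' (a) the herb-network target set and (b) the stage-2 core, and writes
#' every artifact plus a run manifest (configuration, input checksums,
#' per-stage record counts, artifact checksums) to the output
#' directory. All outputs are byte-stable given identical inputs and
#' configuration.
#'
#' @param config a validated configuration (from [validateConfig()]),
#'   a path to a YAML config file, or a named list.
#' @return invisibly, a list with the built networks, screen results,
#'   enrichment tables, the manifest path and the artifact paths.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "PipelineConfig")) config <- validateConfig(config)
  in_keys <- c("herb_table", "chem_table", "ppi_table", "disease_targets",
               "gene_sets", "id_mapping")
  in_paths <- unlist(config[in_keys])
  missing_in <- in_paths[!file.exists(in_paths)]
  if (length(missing_in))
    stop(sprintf("input file not found: %s", missing_in[1]))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  counts <- list()
  artifacts <- character(0)
  manifest_path <- out("manifest.txt")

  result <- tryCatch({
    herb_table <- .stage("read_herb_table", readHerbCompoundTable(config$herb_table))
    chem_in <- .countDataRows(config$chem_table)
    chem <- .stage("read_chem_table",
                   readInteractionTable(config$chem_table, "chemical-protein",
                                        config$chem_score_threshold))
    counts$chem_records <- c(input = chem_in, output = nrow(chem),
                             dropped = chem_in - nrow(chem))
    ppi_in <- .countDataRows(config$ppi_table)
    ppi <- .stage("read_ppi_table",
                  readInteractionTable(config$ppi_table, "protein-protein",
                                       config$ppi_score_threshold))
    counts$ppi_records <- c(input = ppi_in, output = nrow(ppi),
                            dropped = ppi_in - nrow(ppi))
    disease <- .stage("read_disease_targets", readTargetList(config$disease_targets))
    annot <- .stage("read_gene_sets",
                    readGeneSets(config$gene_sets,
                                 backgroundSize = config$enrichment_background))
    if (!is.null(config$id_mapping)) {
      mapping <- .stage("read_id_mapping", readIdMapping(config$id_mapping))
      n_before <- nrow(chem)
      chem <- .stage("map_identifiers",
                     suppressMessages(mapIdentifiers(chem, mapping, policy = "drop")))
      counts$mapped_chem_records <- c(input = n_before, output = nrow(chem),
                                      dropped = n_before - nrow(chem))
    }

    net_ct <- .stage("build_compound_target_network",
                     suppressMessages(buildCompoundTargetNetwork(herb_table, chem)))
    net_htd <- .stage("build_herb_target_disease_network",
                      suppressMessages(buildHerbTargetDiseaseNetwork(herb_table, chem, disease)))
    compound_targets <- unique(chem$target_id)
    net_ppi <- .stage("build_ppi_network",
                      suppressMessages(buildPPINetwork(compound_targets, disease, ppi)))
    seeds_total <- length(union(toupper(compound_targets), toupper(disease)))
    seed_roles <- c("compound_target", "disease_target", "compound_disease_target")
    seeds_kept <- sum(nodeRoles(net_ppi) %in% seed_roles)
    counts$ppi_seeds <- c(input = seeds_total, output = seeds_kept,
                          dropped = seeds_total - seeds_kept)

    artifacts <- c(artifacts,
                   writeNetwork(net_ct, out("compound_target_network"), "sif"),
                   writeNetwork(net_htd, out("herb_target_disease_network"), "sif"),
                   writeNetwork(net_ppi, out("ppi_network"), "sif",
                                centrality = centralityTable(net_ppi)))

    stage1 <- screeningThresholds(config$stage1_degree_min,
                                  config$stage1_betweenness_min,
                                  config$stage1_closeness_min,
                                  mode = config$screen_mode)
    use_top_k <- is.null(config$stage2_degree_min)
    screens <- .stage("two_stage_screen",
      if (use_top_k) twoStageScreen(net_ppi, stage1, topK = config$stage2_top_k)
      else twoStageScreen(net_ppi, stage1,
                          stage2 = screeningThresholds(config$stage2_degree_min,
                                                       config$stage2_betweenness_min,
                                                       config$stage2_closeness_min,
                                                       mode = config$screen_mode)))
    counts$stage1_screen <- c(input = nodeCount(net_ppi),
                              output = nodeCount(screens$stage1$network),
                              dropped = nodeCount(net_ppi) - nodeCount(screens$stage1$network))
    counts$stage2_screen <- c(input = nodeCount(screens$stage1$network),
                              output = nodeCount(screens$stage2$network),
                              dropped = nodeCount(screens$stage1$network) -
                                nodeCount(screens$stage2$network))
    artifacts <- c(artifacts,
                   writeCentralityTable(screens$stage1$table, out("stage1_centrality.tsv")),
                   writeCentralityTable(screens$stage2$table, out("stage2_centrality.tsv")),
                   writeNetwork(screens$stage1$network, out("stage1_subnetwork"), "sif"),
                   writeNetwork(screens$stage2$network, out("stage2_core"), "sif"))

    herb_net_targets <- names(nodeRoles(net_htd))[nodeRoles(net_htd) %in%
                          c("compound_target", "compound_disease_target")]
    enr_targets <- .stage("enrich_herb_network_targets",
                          enrich(herb_net_targets, annot,
                                 minHits = config$enrichment_min_hits,
                                 ease = isTRUE(config$ease)))
    enr_core <- .stage("enrich_core",
                       enrich(nodeIds(screens$stage2$network), annot,
                              minHits = config$enrichment_min_hits,
                              ease = isTRUE(config$ease)))
    artifacts <- c(artifacts,
                   writeEnrichmentTable(enr_targets, out("enrichment_herb_targets.tsv")),
                   writeEnrichmentTable(enr_core, out("enrichment_core.tsv")))
    counts$enrichment <- c(input = length(termIds(annot)),
                           output = nrow(enr_targets) + nrow(enr_core),
                           dropped = NA)

    .writeManifest(manifest_path, config, in_paths, artifacts, counts,
                   status = "complete")
    list(networks = list(compound_target = net_ct,
                         herb_target_disease = net_htd, ppi = net_ppi),
         screens = screens,
         enrichment = list(herb_targets = enr_targets, core = enr_core),
         counts = counts, manifest = manifest_path,
         artifacts = c(artifacts, manifest_path))
  }, error = function(e) {
    .writeManifest(manifest_path, config, in_paths, artifacts, counts,
                   status = "failed", error = conditionMessage(e))
    stop(e)
  })
  invisible(result)
}

.writeManifest <- function(path, config, inputs, artifacts, counts,
                           status, error = NULL) {
  lines <- c(sprintf("status: %s", status))
  if (!is.null(error)) lines <- c(lines, sprintf("error: %s", error))
  cfg <- config[!vapply(config, is.null, logical(1))]
  lines <- c(lines, "", "[config]",
             sprintf("%s: %s", names(cfg),
                     vapply(cfg, function(v) paste(format(v), collapse = ","),
                            character(1))))
  sums <- tools::md5sum(inputs[file.exists(inputs)])
  lines <- c(lines, "", "[inputs]",
             sprintf("%s: %s", basename(names(sums)), unname(sums)))
  if (length(counts)) {
    lines <- c(lines, "", "[counts]")
    for (nm in names(counts))
      lines <- c(lines, sprintf("%s: input=%s output=%s dropped=%s", nm,
                                counts[[nm]]["input"], counts[[nm]]["output"],
                                counts[[nm]]["dropped"]))
  }
  if (length(artifacts)) {
    asums <- tools::md5sum(artifacts[file.exists(artifacts)])
    lines <- c(lines, "", "[artifacts]",
               sprintf("%s: %s", basename(names(asums)), unname(asums)))
  }
  writeLines(lines, path)
  invisible(path)
}
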