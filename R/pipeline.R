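#' Run the full prioritization pipeline
#'
#' End-to-end orchestration: load inputs, optionally derive the TSG seed
#' list from a similarity table via the orthology stage, reconstruct the
#' aging and TSG first-neighbour networks, merge and partition them into
#' the eight clusters, compute graph statistics, rank candidate genes by
#' combined degree/betweenness rank, run GO over-representation of each top
#' candidate's secondary neighbourhood, score candidates by semantic
#' similarity to the known-aging reference, and compute the a-priori
#' probability report. All artifacts are written under `output_dir`.
#'
#' @param config path to a YAML config file, or an equivalent nested list.
#'   Recognised entries: `inputs$interactions` (required),
#'   `inputs$aging_seeds` (required), `inputs$tsg_seeds` and/or
#'   `inputs$similarity_table`, `inputs$known_aging`, `inputs$synonyms`,
#'   `inputs$obo` + `inputs$gaf`, `inputs$slim_terms`, `inputs$lrg`;
#'   `params$class_filter`, `params$top_k` (default 3),
#'   `params$radius` (default 2), `params$fdr_cutoff` (default 0.5),
#'   `params$semsim_threshold` (default 0.9), `params$hub_top_fraction`
#'   (default 0.1), `params$evalue_cutoff` (1e-5), `params$inflation`
#'   (1.5), `params$rank_scope` ("pool" or "global"). Relative input paths
#'   are resolved against the config file's directory.
#' @param output_dir directory for the run artifacts (default: a
#'   `longevnet-run` directory next to the config, created if needed).
#' @return an object of class `run_report` (a nested list, also written as
#'   `report.json`): input checksums, network sizes, cluster sizes 1-8,
#'   candidate table, enrichment tables, semantic-similarity scores, prior
#'   estimates, warning counts and run status.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    cfg_path <- normalizePath(config)
    cfg <- yaml::read_yaml(cfg_path)
    base_dir <- dirname(cfg_path)
  } else {
    cfg <- config
    base_dir <- getwd()
  }
  inputs <- cfg$inputs %||% list()
  params <- cfg$params %||% list()
  p <- list(
    class_filter = params$class_filter %||% NULL,
    top_k = as.integer(params$top_k %||% 3L),
    radius = as.integer(params$radius %||% 2L),
    fdr_cutoff = params$fdr_cutoff %||% 0.5,
    semsim_threshold = params$semsim_threshold %||% 0.9,
    hub_top_fraction = params$hub_top_fraction %||% 0.1,
    evalue_cutoff = params$evalue_cutoff %||% 1e-5,
    inflation = params$inflation %||% 1.5,
    rank_scope = params$rank_scope %||% "pool"
  )
  resolve <- function(path) {
    if (is.null(path)) return(NULL)
    if (file.exists(path)) normalizePath(path) else
      normalizePath(file.path(base_dir, path), mustWork = TRUE)
  }
  stage <- function(name, expr) {
    message("[longevnet] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(inputs$interactions) || is.null(inputs$aging_seeds)) {
    stop("config must name inputs$interactions and inputs$aging_seeds")
  }
  in_paths <- lapply(inputs, resolve)
  checksums <- vapply(in_paths[!vapply(in_paths, is.null, TRUE)],
                      function(f) unname(tools::md5sum(f)), "")
  out_dir <- output_dir %||% file.path(base_dir, "longevnet-run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  syn <- if (!is.null(in_paths$synonyms)) {
    stage("synonyms", read_synonym_table(in_paths$synonyms))
  } else NULL
  records <- stage("interactions", read_interaction_table(
    in_paths$interactions, class_filter = p$class_filter, synonyms = syn))
  aging_seeds <- stage("aging seeds", {
    res <- resolve_synonyms(read_gene_list(in_paths$aging_seeds),
                            syn %||% synonym_map())
    gene_set(res$symbols, "aging")
  })
  warn_counts <- list()
  tsg_seeds <- if (!is.null(in_paths$tsg_seeds)) {
    res <- stage("tsg seeds", resolve_synonyms(
      read_gene_list(in_paths$tsg_seeds), syn %||% synonym_map()))
    warn_counts$tsg_synonym_collisions <- res$n_collisions
    gene_set(res$symbols, "tsg")
  } else if (!is.null(in_paths$similarity_table)) {
    stage("ortholog clustering", {
      sim <- read_similarity_table(in_paths$similarity_table)
      oc <- ortholog_clusters(
        sim, ortholog_params(evalue_cutoff = p$evalue_cutoff,
                             inflation = p$inflation),
        from_species = "HUMAN", to_species = "WORM")
      write_cluster_table(oc$clusters, file.path(out_dir, "ortholog_clusters.tsv"))
      gene_set(unlist(oc$map, use.names = FALSE), "tsg")
    })
  } else {
    gene_set(name = "tsg")
  }
  known_aging <- if (!is.null(in_paths$known_aging)) {
    read_gene_list(in_paths$known_aging, "known_aging")
  } else {
    gene_set(name = "known_aging")
  }

  aging_net <- stage("aging network",
                     reconstruct_query_network(aging_seeds, records))
  tsg_net <- stage("tsg network",
                   reconstruct_query_network(tsg_seeds, records))
  merged <- stage("merge", {
    m <- merge_networks(aging_net, tsg_net)
    set_seed_flags(m, aging_seeds, tsg_seeds)
  })
  write_xgmml(merged, file.path(out_dir, "merged.xgmml"), label = "merged")
  partition <- stage("partition", partition_clusters(
    merged, aging_net, tsg_net, aging_seeds, tsg_seeds))
  write_partition_tsv(partition, merged, file.path(out_dir, "partition.tsv"))
  stats_all <- stage("graph statistics", list(
    aging = network_stats(aging_net),
    tsg = network_stats(tsg_net),
    merged = network_stats(merged)
  ))
  write_centrality_table(centrality_table(merged),
                         file.path(out_dir, "centrality.tsv"))
  candidates <- stage("candidate ranking", select_candidates(
    partition, known_aging, merged, k = p$top_k, scope = p$rank_scope))
  write_centrality_table(candidates$table, file.path(out_dir, "candidates.tsv"))

  enrichments <- list()
  semsim_scores <- NULL
  if (!is.null(in_paths$obo) && !is.null(in_paths$gaf) &&
      nrow(candidates$top) > 0) {
    onta <- stage("ontology", read_ontology_annotations(in_paths$obo,
                                                        in_paths$gaf))
    slim <- if (!is.null(in_paths$slim_terms)) {
      readLines(in_paths$slim_terms, warn = FALSE)
    } else NULL
    population <- gene_set(network_genes(merged), "merged")
    for (gene in candidates$top$gene) {
      tab <- stage(paste0("enrichment: ", gene), {
        study <- gene_set(network_genes(
          neighborhood_network(merged, gene, p$radius)), gene)
        enrich(study, population, onta$ontology, onta$annotations,
               fdr_cutoff = p$fdr_cutoff, slim_terms = slim)
      })
      enrichments[[gene]] <- tab
      write_enrichment_tsv(tab, file.path(out_dir,
                                          paste0("enrichment_", gene, ".tsv")))
    }
    ref <- gene_set(intersect(as_members(known_aging),
                              names(onta$annotations)), "reference")
    if (length(ref) > 0) {
      semsim <- stage("semantic similarity", filter_by_semsim(
        gene_set(candidates$top$gene), ref, onta$ontology, onta$annotations,
        threshold = p$semsim_threshold))
      semsim_scores <- semsim$scores
      utils::write.table(semsim_scores,
                         file.path(out_dir, "semsim_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  prior <- if (!is.null(in_paths$lrg)) {
    stage("prior probabilities", prior_report(
      gene_set(unique(c(records$gene_a, records$gene_b)), "universe"),
      gene_set(intersect(as_members(read_gene_list(in_paths$lrg)),
                         c(records$gene_a, records$gene_b)), "lrg"),
      net = merged, top_fraction = p$hub_top_fraction))
  } else NULL

  report <- structure(list(
    package_version = as.character(utils::packageVersion("longevnet")),
    config_hash = .config_hash(cfg),
    input_checksums = as.list(checksums),
    params = p,
    networks = stats_all,
    aging_report = attr(aging_net, "report"),
    tsg_report = attr(tsg_net, "report"),
    cluster_sizes = as.list(cluster_sizes(partition)),
    partition_anomalies = partition$anomalies,
    pool_size = candidates$pool_size,
    n_known_excluded = length(candidates$excluded_known),
    top_candidates = candidates$top,
    enrichment = lapply(enrichments, function(tab)
      utils::head(as.data.frame(tab), 10L)),
    semsim_scores = semsim_scores,
    prior = if (!is.null(prior)) unclass(prior) else NULL,
    warnings = warn_counts,
    status = if (candidates$pool_size == 0L) "no candidates" else "ok"
  ), class = "run_report")
  jsonlite::write_json(.report_jsonable(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  report
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.report_jsonable <- function(x) {
  if (inherits(x, "data.frame")) return(x)
  if (is.list(x)) return(lapply(x, .report_jsonable))
  x
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  status:", x$status, "\n")
  cat("  merged network:", x$networks$merged$n_nodes, "nodes,",
      x$networks$merged$n_edges, "edges\n")
  cat("  cluster sizes:", paste(unlist(x$cluster_sizes), collapse = " "), "\n")
  cat("  candidate pool:", x$pool_size, "genes (",
      x$n_known_excluded, "known-aging excluded )\n")
  if (nrow(x$top_candidates)) {
    cat("  top candidates:",
        paste(x$top_candidates$gene, collapse = ", "), "\n")
  }
  invisible(x)
}
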