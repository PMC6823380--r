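#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the real study conditions: a hub-heavy
#' preferential-attachment PPI network at the scale of the curated worm
#' interactome (3000 genes, about 9000 interactions), a 0.35% genome-wide
#' rate of lifespan-reduction genes (LRGs) enriched to 5% among hub nodes,
#' aging/TSG seed lists of 741 and 464 genes, and a small GO DAG with
#' planted term enrichment. The hub stratum used for LRG planting is the
#' top `hub_top_fraction` of nodes by degree; it defaults to 3% because a
#' 5% LRG rate on a larger hub stratum would exceed what a 0.35% global
#' rate can supply (at 10% hubs, 0.10 x 0.05 = 0.005 > 0.0035).
#'
#' @param n_genes universe size.
#' @param lrg_fraction global LRG rate.
#' @param hub_lrg_fraction LRG rate planted among hub nodes.
#' @param hub_top_fraction degree-quantile fraction defining the hub
#'   stratum for planting.
#' @param attachment_m edges attached per node in the preferential
#'   attachment model (total edges ~ `attachment_m * n_genes`).
#' @param n_aging_seeds,n_tsg_seeds seed list sizes.
#' @param seed_overlap_fraction overlap between the two seed lists as a
#'   fraction of the smaller list.
#' @param known_aging_fraction fraction of the overlap treated as genes
#'   with an already-reported aging role.
#' @param ontology_depth number of levels in the generated GO DAG
#'   (1 = a single root).
#' @param ontology_branching children per term between levels.
#' @param annotation_rate baseline probability that a gene is annotated to
#'   a given leaf term.
#' @param planted_fold annotation-rate multiplier for planted terms inside
#'   the target neighbourhood.
#' @param n_planted_terms number of planted (enriched) leaf terms.
#' @param n_ortholog_clusters number of planted ortholog clusters.
#' @param genes_per_cluster genes per ortholog cluster (2 or 3: one human
#'   gene plus one or two worm co-orthologs; larger clusters cannot stay
#'   connected under a pure reciprocal-best-hit graph).
#' @param n_background_pairs number of between-cluster similarity rows
#'   (e-values above the cutoff).
#' @param rng_seed integer seed; all generators are pure functions of the
#'   config including this seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_genes = 3000L,
                         lrg_fraction = 0.0035,
                         hub_lrg_fraction = 0.05,
                         hub_top_fraction = 0.03,
                         attachment_m = 3L,
                         n_aging_seeds = 741L,
                         n_tsg_seeds = 464L,
                         seed_overlap_fraction = 0.16,
                         known_aging_fraction = 0.34,
                         ontology_depth = 4L,
                         ontology_branching = 3L,
                         annotation_rate = 0.08,
                         planted_fold = 5,
                         n_planted_terms = 2L,
                         n_ortholog_clusters = 20L,
                         genes_per_cluster = 2L,
                         n_background_pairs = 30L,
                         rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), lrg_fraction = lrg_fraction,
              hub_lrg_fraction = hub_lrg_fraction,
              hub_top_fraction = hub_top_fraction,
              attachment_m = as.integer(attachment_m),
              n_aging_seeds = as.integer(n_aging_seeds),
              n_tsg_seeds = as.integer(n_tsg_seeds),
              seed_overlap_fraction = seed_overlap_fraction,
              known_aging_fraction = known_aging_fraction,
              ontology_depth = as.integer(ontology_depth),
              ontology_branching = as.integer(ontology_branching),
              annotation_rate = annotation_rate,
              planted_fold = planted_fold,
              n_planted_terms = as.integer(n_planted_terms),
              n_ortholog_clusters = as.integer(n_ortholog_clusters),
              genes_per_cluster = as.integer(genes_per_cluster),
              n_background_pairs = as.integer(n_background_pairs),
              rng_seed = as.integer(rng_seed))
  fr <- c(cfg$lrg_fraction, cfg$hub_lrg_fraction, cfg$hub_top_fraction,
          cfg$seed_overlap_fraction, cfg$known_aging_fraction,
          cfg$annotation_rate)
  stopifnot(all(fr >= 0), all(fr <= 1), cfg$hub_top_fraction > 0,
            cfg$n_genes > 0, cfg$attachment_m >= 1,
            cfg$ontology_depth >= 1, cfg$ontology_branching >= 1,
            cfg$planted_fold >= 0, cfg$n_ortholog_clusters >= 1)
  if (!cfg$genes_per_cluster %in% c(2L, 3L)) {
    stop("genes_per_cluster must be 2 or 3: a pure reciprocal-best-hit ",
         "graph cannot keep larger planted clusters connected")
  }
  structure(cfg, class = "synth_config")
}

.gene_ids <- function(n) sprintf("G%05d", seq_len(n))

#' Generate the gene universe, LRG labels and interaction records
#'
#' Builds an undirected preferential-attachment graph (hub-heavy degree
#' distribution) over the universe and plants LRG labels by stratified
#' sampling: the configured number of LRGs among the hub stratum (top
#' `hub_top_fraction` of nodes by degree, inclusive of cutoff ties) and the
#' remainder among non-hubs, so the global rate is `lrg_fraction` and the
#' hub rate is `hub_lrg_fraction`. Labels are assigned after graph
#' construction and cannot change the topology.
#'
#' @param config a `synth_config`.
#' @return list with `universe` (`gene_set`), `lrg` (`gene_set`), `records`
#'   (interaction data.frame, class `physical`), `network` (`ppi_network`).
#' @export
gen_universe_and_network <- function(config) {
  set.seed(config$rng_seed)
  n <- config$n_genes
  genes <- .gene_ids(n)
  g <- igraph::sample_pa(n, m = config$attachment_m, directed = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  records <- data.frame(
    gene_a = genes[as.integer(el[, 1L])],
    gene_b = genes[as.integer(el[, 2L])],
    interaction_class = "physical",
    source_id = sprintf("SYN-%06d", seq_len(nrow(el))),
    stringsAsFactors = FALSE
  )
  records <- records[records$gene_a != records$gene_b, , drop = FALSE]
  net <- build_network(records)
  n_lrg <- round(n * config$lrg_fraction)
  if (n_lrg == 0L) {
    return(list(universe = gene_set(genes, "universe"),
                lrg = gene_set(name = "lrg"),
                records = records, network = net))
  }
  hub_genes <- hubs(net, config$hub_top_fraction)$members
  quota <- round(length(hub_genes) * config$hub_lrg_fraction)
  non_hub <- setdiff(genes, hub_genes)
  if (quota > n_lrg || quota > length(hub_genes) ||
      (n_lrg - quota) > length(non_hub)) {
    stop("infeasible LRG fractions: hub quota ", quota,
         " exceeds what a global rate of ", config$lrg_fraction,
         " over ", n, " genes can supply")
  }
  lrg <- c(sample(hub_genes, quota), sample(non_hub, n_lrg - quota))
  list(universe = gene_set(genes, "universe"),
       lrg = gene_set(lrg, "lrg"),
       records = records, network = net)
}

#' Generate the aging and TSG seed lists
#'
#' Two seed lists with a configured overlap, plus the subset of the overlap
#' treated as genes with an already-reported aging role.
#'
#' @param config a `synth_config`.
#' @param universe `gene_set` from [gen_universe_and_network()].
#' @return list with `aging`, `tsg`, `known_aging_tsg` (`gene_set`s).
#' @export
gen_seed_lists <- function(config, universe) {
  set.seed(config$rng_seed + 1L)
  u <- as_members(universe)
  na <- config$n_aging_seeds
  nt <- config$n_tsg_seeds
  overlap <- round(config$seed_overlap_fraction * min(na, nt))
  if (overlap > na || overlap > nt) {
    stop("seed overlap larger than a seed list")
  }
  if (na + nt - overlap > length(u)) {
    stop("universe too small for the requested seed lists")
  }
  shared <- sample(u, overlap)
  rest <- setdiff(u, shared)
  aging_extra <- sample(rest, na - overlap)
  tsg_extra <- sample(setdiff(rest, aging_extra), nt - overlap)
  known <- if (overlap) {
    sample(shared, round(config$known_aging_fraction * overlap))
  } else {
    character()
  }
  list(aging = gene_set(c(shared, aging_extra), "aging"),
       tsg = gene_set(c(shared, tsg_extra), "tsg"),
       known_aging_tsg = gene_set(known, "known_aging"))
}

#' Generate a GO DAG and annotations with planted enrichment
#'
#' Builds a layered random DAG (`ontology_depth` levels, `ontology_branching`
#' children per term, occasional second parents) and annotates every gene to
#' leaf terms at the baseline rate. The planted leaf terms are annotated at
#' `planted_fold` times the baseline rate inside the target neighbourhood,
#' giving a known enrichment ground truth.
#'
#' @param config a `synth_config`.
#' @param universe `gene_set` of genes to annotate.
#' @param target_neighborhood `gene_set` (subset of universe) in which the
#'   planted terms are enriched.
#' @return list with `ontology`, `annotations` (named list gene -> direct
#'   terms), `planted_terms` (character).
#' @export
gen_ontology_annotations <- function(config, universe, target_neighborhood) {
  set.seed(config$rng_seed + 2L)
  u <- as_members(universe)
  target <- as_members(target_neighborhood)
  if (!all(target %in% u)) stop("target neighbourhood not inside universe")
  depth <- config$ontology_depth
  levels <- vector("list", depth)
  counter <- 0L
  new_terms <- function(k) {
    ids <- sprintf("GO:%07d", counter + seq_len(k))
    counter <<- counter + k
    ids
  }
  levels[[1L]] <- new_terms(1L)
  parents <- list()
  if (depth > 1L) {
    for (l in 2:depth) {
      k <- min(config$ontology_branching ^ (l - 1L), 200L)
      levels[[l]] <- new_terms(k)
      for (t in levels[[l]]) {
        p <- sample(levels[[l - 1L]], 1L)
        if (length(levels[[l - 1L]]) > 1L && stats::runif(1) < 0.2) {
          p <- unique(c(p, sample(setdiff(levels[[l - 1L]], p), 1L)))
        }
        parents[[t]] <- p
      }
    }
  }
  terms <- unlist(levels, use.names = FALSE)
  ont <- ontology(terms, paste("term", terms), parents)
  leaves <- levels[[depth]]
  planted <- sort(sample(leaves, min(config$n_planted_terms, length(leaves))))
  base <- config$annotation_rate
  boost <- min(1, base * config$planted_fold)
  prob <- matrix(base, nrow = length(u), ncol = length(leaves),
                 dimnames = list(u, leaves))
  prob[u %in% target, leaves %in% planted] <- boost
  hitmat <- matrix(stats::runif(length(prob)), nrow = nrow(prob)) < prob
  ann <- lapply(seq_along(u), function(i) leaves[hitmat[i, ]])
  names(ann) <- u
  empty <- lengths(ann) == 0L
  if (any(empty)) {
    ann[empty] <- as.list(sample(leaves, sum(empty), replace = TRUE))
  }
  ann <- lapply(ann, function(x) sort(unique(x)))
  list(ontology = ont, annotations = ann, planted_terms = planted)
}

#' Generate a two-species similarity table with planted ortholog clusters
#'
#' Each planted cluster holds one human gene and one or two worm genes. All
#' within-cluster ordered pairs (cross- and same-species) get e-values
#' log-uniform in \[1e-180, 1e-20\]; between-cluster background rows get
#' e-values in \[1e-4, 1\], above the default 1e-5 cutoff, so reciprocal
#' best hits are consistent with the planted clusters by construction.
#'
#' @param config a `synth_config`.
#' @param worm_genes optional character vector to draw worm symbols from
#'   (defaults to generated `WORMnnnn` symbols).
#' @return list with `records` (similarity data.frame), `true_clusters`
#'   (list of `SPECIES|SYMBOL` vectors), `human_genes`, `worm_genes`.
#' @export
gen_similarity_table <- function(config, worm_genes = NULL) {
  set.seed(config$rng_seed + 3L)
  n_cl <- config$n_ortholog_clusters
  per <- config$genes_per_cluster
  n_worm <- n_cl * (per - 1L)
  humans <- sprintf("HTSG%03d", seq_len(n_cl))
  worms <- if (is.null(worm_genes)) {
    sprintf("WORM%04d", seq_len(n_worm))
  } else {
    worm_genes <- canonical_symbols(worm_genes)
    if (length(worm_genes) < n_worm) stop("not enough worm genes supplied")
    sample(worm_genes, n_worm)
  }
  species_of <- c(stats::setNames(rep("HUMAN", n_cl), humans),
                  stats::setNames(rep("WORM", n_worm), worms))
  clusters <- vector("list", n_cl)
  rows <- list()
  wi <- 0L
  for (i in seq_len(n_cl)) {
    members <- c(humans[i], worms[wi + seq_len(per - 1L)])
    wi <- wi + (per - 1L)
    clusters[[i]] <- sort(.node_key(species_of[members], members))
    for (qa in members) for (sa in setdiff(members, qa)) {
      rows[[length(rows) + 1L]] <- data.frame(
        query = qa, subject = sa,
        query_species = species_of[[qa]], subject_species = species_of[[sa]],
        evalue = 10 ^ stats::runif(1, -180, -20),
        bitscore = stats::runif(1, 200, 1000),
        stringsAsFactors = FALSE
      )
    }
  }
  if (config$n_background_pairs > 0L && n_cl > 1L) {
    for (b in seq_len(config$n_background_pairs)) {
      ci <- sample(n_cl, 2L)
      h <- humans[ci[1L]]
      w_pool <- setdiff(worms, sub("^WORM\\|", "",
                                   grep("^WORM\\|", clusters[[ci[1L]]],
                                        value = TRUE)))
      w <- sample(w_pool, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        query = h, subject = w, query_species = "HUMAN",
        subject_species = "WORM",
        evalue = 10 ^ stats::runif(1, -4, 0),
        bitscore = stats::runif(1, 20, 50),
        stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, rows)
  records$query <- canonical_symbols(records$query)
  records$subject <- canonical_symbols(records$subject)
  list(records = records, true_clusters = clusters,
       human_genes = humans, worm_genes = worms)
}

#' Write a complete synthetic fixture directory
#'
#' Generates every input the pipeline consumes and writes them as plain
#' text: `interactions.tsv`, `aging.txt`, `tsg.txt`, `known_aging.txt`,
#' `lrg.txt`, `synonyms.tsv`, `go.obo`, `annotations.gaf`, `blast.tsv`,
#' `truth.json` (the planted ground truth) and a ready-to-run pipeline
#' config `config.yaml`. The enrichment target neighbourhood is the
#' radius-2 neighbourhood of the highest-degree TSG seed present in the
#' network.
#'
#' @param config a `synth_config`.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written file paths plus the
#'   in-memory `truth` list.
#' @export
generate_fixture_dir <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  uni <- gen_universe_and_network(config)
  seeds <- gen_seed_lists(config, uni$universe)
  net_genes <- network_genes(uni$network)
  deg <- node_degree(uni$network)
  tsg_in_net <- intersect(seeds$tsg$members, net_genes)
  anchor <- if (length(tsg_in_net)) {
    tsg_in_net[which.max(deg[tsg_in_net])]
  } else {
    names(deg)[which.max(deg)]
  }
  target <- network_genes(neighborhood_network(uni$network, anchor, 2L))
  go <- gen_ontology_annotations(config, uni$universe, target)
  sim <- gen_similarity_table(config, worm_genes = seeds$tsg$members)
  set.seed(config$rng_seed + 4L)
  alias_src <- sample(as_members(uni$universe), min(20L, config$n_genes))
  syn_tab <- data.frame(alias = paste0("ALIAS_", alias_src),
                        canonical = alias_src, stringsAsFactors = FALSE)
  paths <- list(
    interactions = file.path(dir, "interactions.tsv"),
    aging = file.path(dir, "aging.txt"),
    tsg = file.path(dir, "tsg.txt"),
    known_aging = file.path(dir, "known_aging.txt"),
    lrg = file.path(dir, "lrg.txt"),
    synonyms = file.path(dir, "synonyms.tsv"),
    obo = file.path(dir, "go.obo"),
    gaf = file.path(dir, "annotations.gaf"),
    blast = file.path(dir, "blast.tsv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml")
  )
  write_interaction_table(uni$records, paths$interactions)
  write_gene_list(seeds$aging, paths$aging)
  write_gene_list(seeds$tsg, paths$tsg)
  write_gene_list(seeds$known_aging_tsg, paths$known_aging)
  write_gene_list(uni$lrg, paths$lrg)
  utils::write.table(syn_tab, paths$synonyms, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_obo(go$ontology, paths$obo)
  write_gaf(go$annotations, paths$gaf)
  write_similarity_table(sim$records, paths$blast)
  truth <- list(
    lrg = uni$lrg$members,
    aging_seeds = seeds$aging$members,
    tsg_seeds = seeds$tsg$members,
    known_aging = seeds$known_aging_tsg$members,
    planted_terms = go$planted_terms,
    enrichment_anchor = anchor,
    target_neighborhood = target,
    ortholog_clusters = sim$true_clusters,
    rng_seed = config$rng_seed
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  run_cfg <- list(
    inputs = list(
      interactions = "interactions.tsv",
      aging_seeds = "aging.txt",
      tsg_seeds = "tsg.txt",
      known_aging = "known_aging.txt",
      lrg = "lrg.txt",
      synonyms = "synonyms.tsv",
      obo = "go.obo",
      gaf = "annotations.gaf"
    ),
    params = list(
      class_filter = NULL, top_k = 3L, radius = 2L, fdr_cutoff = 0.5,
      semsim_threshold = 0.9, hub_top_fraction = config$hub_top_fraction,
      evalue_cutoff = 1e-5, inflation = 1.5, rank_scope = "pool"
    )
  )
  yaml::write_yaml(run_cfg, paths$config)
  invisible(c(paths, list(truth_data = truth)))
}
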