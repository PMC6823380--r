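#' Reconstruct a first-neighbour query network
#'
#' Keeps exactly the interactions with at least one endpoint in the query
#' set; nodes are the query genes that have interactions plus their
#' interactors. A report of query coverage is attached as the `"report"`
#' attribute: `n_query_hit` (queries present in the network),
#' `n_interactions` (unique undirected edges) and `n_unique_interactors`
#' (non-query nodes).
#'
#' @param queries a `gene_set` (or character vector) of canonical query
#'   symbols.
#' @param records interaction data.frame (columns `gene_a`, `gene_b`).
#' @return a `ppi_network` with the `"report"` attribute.
#' @export
reconstruct_query_network <- function(queries, records) {
  q <- as_members(queries)
  a <- canonical_symbols(records$gene_a)
  b <- canonical_symbols(records$gene_b)
  keep <- a %in% q | b %in% q
  net <- build_network(data.frame(gene_a = a[keep], gene_b = b[keep],
                                  stringsAsFactors = FALSE))
  attr(net, "report") <- list(
    n_query_hit = length(intersect(q, network_genes(net))),
    n_interactions = n_edges(net),
    n_unique_interactors = length(setdiff(network_genes(net), q))
  )
  net
}

#' Partition the merged network into the eight aging/TSG clusters
#'
#' Every node of the merged network is assigned to exactly one of eight
#' clusters defined from the aging-network node set A, the TSG-network node
#' set T, their intersection I (the "connector" genes) and the two seed
#' sets Sa (aging) and St (TSG):
#'
#' 1. aging-only nodes that are aging seeds;
#' 2. aging-only interactors (no seed annotation);
#' 3. connectors annotated as aging seeds only;
#' 4. connectors annotated as both aging and TSG seeds;
#' 5. connectors with no seed annotation;
#' 6. connectors annotated as TSG seeds only;
#' 7. TSG-only interactors (no seed annotation);
#' 8. TSG-only nodes that are TSG seeds.
#'
#' Two anomalous combinations (a TSG seed appearing only in the aging
#' network, or an aging seed appearing only in the TSG network) fall into
#' the interactor clusters 2 and 7 respectively and are counted in the
#' `anomalies` element.
#'
#' @param merged merged `ppi_network`; its node set must equal the union of
#'   the two subnetwork node sets.
#' @param aging_net,tsg_net the two component `ppi_network`s.
#' @param aging_seeds,tsg_seeds seed `gene_set`s (or character vectors).
#' @return an object of class `cluster_partition`: list with `assignment`
#'   (named integer vector gene -> 1..8), `clusters` (named list `"1"`..`"8"`
#'   of sorted member vectors, always all eight labels present), `anomalies`.
#' @export
partition_clusters <- function(merged, aging_net, tsg_net,
                               aging_seeds, tsg_seeds) {
  A <- network_genes(aging_net)
  T_ <- network_genes(tsg_net)
  M <- network_genes(merged)
  if (!setequal(M, union(A, T_))) {
    stop("merged node set must equal the union of the aging and TSG ",
         "networks; offending node(s): ",
         paste(c(setdiff(M, union(A, T_)), setdiff(union(A, T_), M)),
               collapse = ", "))
  }
  Sa <- as_members(aging_seeds)
  St <- as_members(tsg_seeds)
  in_A <- M %in% A
  in_T <- M %in% T_
  in_Sa <- M %in% Sa
  in_St <- M %in% St
  cl <- integer(length(M))
  only_A <- in_A & !in_T
  only_T <- in_T & !in_A
  both <- in_A & in_T
  cl[only_A & in_Sa] <- 1L
  cl[only_A & !in_Sa] <- 2L
  cl[both & in_Sa & !in_St] <- 3L
  cl[both & in_Sa & in_St] <- 4L
  cl[both & !in_Sa & !in_St] <- 5L
  cl[both & !in_Sa & in_St] <- 6L
  cl[only_T & !in_St] <- 7L
  cl[only_T & in_St] <- 8L
  stopifnot(all(cl >= 1L), all(cl <= 8L))
  assignment <- stats::setNames(cl, M)
  clusters <- stats::setNames(
    lapply(1:8, function(i) sort(M[cl == i])), as.character(1:8))
  anomalies <- list(
    tsg_seed_in_aging_only = sum(only_A & in_St & !in_Sa),
    aging_seed_in_tsg_only = sum(only_T & in_Sa & !in_St)
  )
  structure(list(assignment = assignment, clusters = clusters,
                 anomalies = anomalies),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  sizes <- vapply(x$clusters, length, 1L)
  cat("<cluster_partition>\n")
  print(sizes)
  invisible(x)
}

#' Cluster sizes of a partition
#' @param partition a `cluster_partition`.
#' @return named integer vector of the eight cluster sizes.
#' @export
cluster_sizes <- function(partition) {
  vapply(partition$clusters, length, 1L)
}

#' Write a cluster partition as TSV
#'
#' Columns: gene, cluster, is_aging_seed, is_tsg_seed.
#'
#' @param partition a `cluster_partition`.
#' @param net the merged `ppi_network` (source of the seed flags).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_partition_tsv <- function(partition, net, path) {
  genes <- names(partition$assignment)
  idx <- match(genes, net$nodes$gene)
  out <- data.frame(
    gene = genes,
    cluster = as.integer(partition$assignment),
    is_aging_seed = net$nodes$is_aging_seed[idx],
    is_tsg_seed = net$nodes$is_tsg_seed[idx],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$cluster, out$gene), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
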