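#' Node degree
#'
#' Number of distinct neighbours of every node (the graph is simple, so
#' degree equals neighbour count).
#'
#' @param net a `ppi_network`.
#' @return named numeric vector over all nodes (isolated nodes score 0).
#' @export
node_degree <- function(net) {
  if (n_nodes(net) == 0L) return(stats::setNames(numeric(), character()))
  deg <- stats::setNames(numeric(n_nodes(net)), network_genes(net))
  if (n_edges(net)) {
    tab <- table(c(net$edges$from, net$edges$to))
    deg[names(tab)] <- as.numeric(tab)
  }
  deg
}

#' Shortest-path betweenness centrality
#'
#' Unnormalized, undirected betweenness with fractional counting over
#' multiple geodesics and endpoints excluded, computed per connected
#' component (each unordered pair of distinct, connected nodes contributes
#' total weight one, split over its shortest paths).
#'
#' @param net a `ppi_network`.
#' @return named numeric vector over all nodes.
#' @export
node_betweenness <- function(net) {
  if (n_nodes(net) == 0L) return(stats::setNames(numeric(), character()))
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  stats::setNames(as.numeric(b), names(b))[network_genes(net)]
}

#' Network diameter
#'
#' Largest finite shortest-path distance; for disconnected graphs the
#' maximum is over components. An edgeless network has diameter 0.
#'
#' @param net a nonempty `ppi_network`.
#' @return integer distance.
#' @export
network_diameter <- function(net) {
  if (n_nodes(net) == 0L) stop("network is empty")
  if (n_edges(net) == 0L) return(0L)
  as.integer(igraph::diameter(as_igraph(net), directed = FALSE,
                              unconnected = TRUE))
}

#' Mean shortest-path length
#'
#' Mean over all connected ordered pairs of distinct nodes; infinite
#' distances (pairs in different components) are excluded. `NA` when the
#' network has no edges (no finite pair exists).
#'
#' @param net a nonempty `ppi_network`.
#' @return numeric, or `NA_real_` for an edgeless network.
#' @export
mean_path_length <- function(net) {
  if (n_nodes(net) == 0L) stop("network is empty")
  if (n_edges(net) == 0L) return(NA_real_)
  igraph::mean_distance(as_igraph(net), directed = FALSE, unconnected = TRUE)
}

#' Number of connected components
#' @param net a `ppi_network`.
#' @return integer count (isolated nodes count as components).
#' @export
n_components <- function(net) {
  if (n_nodes(net) == 0L) return(0L)
  igraph::components(as_igraph(net))$no
}

#' Summary statistics of a network
#' @param net a `ppi_network`.
#' @return list with `n_nodes`, `n_edges`, `n_components`, `diameter`,
#'   `mean_path_length`.
#' @export
network_stats <- function(net) {
  list(
    n_nodes = n_nodes(net),
    n_edges = n_edges(net),
    n_components = n_components(net),
    diameter = if (n_nodes(net)) network_diameter(net) else NA_integer_,
    mean_path_length = if (n_nodes(net)) mean_path_length(net) else NA_real_
  )
}

#' Neighbourhood subnetwork of a seed gene
#'
#' Induced subgraph on all nodes within shortest-path distance `radius` of
#' the seed; radius 2 corresponds to the seed's secondary connections.
#'
#' @param net a `ppi_network`.
#' @param seed seed gene symbol (canonicalized on entry).
#' @param radius non-negative integer distance bound.
#' @return a `ppi_network`.
#' @export
neighborhood_network <- function(net, seed, radius = 2L) {
  seed <- canonical_symbols(seed)
  stopifnot(length(seed) == 1L, radius >= 0)
  if (!seed %in% network_genes(net)) {
    stop("seed gene '", seed, "' is not in the network")
  }
  if (radius == 0 || n_edges(net) == 0L) {
    return(induced_network(net, seed))
  }
  d <- igraph::distances(as_igraph(net), v = seed)
  induced_network(net, colnames(d)[d[1L, ] <= radius])
}

#' Hub nodes by degree quantile
#'
#' The top `top_fraction` of nodes by degree, with all nodes tied at the
#' cutoff degree included (so the returned set can be slightly larger than
#' `top_fraction * n`).
#'
#' @param net a `ppi_network`.
#' @param top_fraction fraction in (0, 1].
#' @return a `gene_set` of hub genes.
#' @export
hubs <- function(net, top_fraction = 0.1) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  if (n_nodes(net) == 0L) return(gene_set(name = "hubs"))
  deg <- node_degree(net)
  k <- ceiling(top_fraction * length(deg))
  cutoff <- sort(deg, decreasing = TRUE)[k]
  gene_set(names(deg)[deg >= cutoff], name = "hubs")
}

#' Per-gene centrality table with ranks
#'
#' Degree, betweenness and their competition ranks (rank 1 = highest score;
#' ties share the smallest applicable rank), plus the combined rank
#' `rank_min = rank_de + rank_be`, the prioritization score (smaller is
#' better). Rows are ordered by `rank_min`, ties broken lexicographically.
#'
#' @param net a `ppi_network`.
#' @return data.frame with columns `gene`, `degree`, `betweenness`,
#'   `rank_de`, `rank_be`, `rank_min`.
#' @export
centrality_table <- function(net) {
  deg <- node_degree(net)
  btw <- node_betweenness(net)
  rank_de <- rank_scores(deg)
  rank_be <- rank_scores(btw)
  rmin <- rank_min(rank_de, rank_be)
  out <- data.frame(
    gene = names(deg),
    degree = as.numeric(deg),
    betweenness = as.numeric(btw[names(deg)]),
    rank_de = as.integer(rank_de[names(deg)]),
    rank_be = as.integer(rank_be[names(deg)]),
    rank_min = as.integer(rmin[names(deg)]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rank_min, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a centrality table as TSV
#' @param tab data.frame from [centrality_table()] or [select_candidates()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_centrality_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
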