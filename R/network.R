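#' Undirected simple PPI network
#'
#' The package's graph container: a node table (`gene`, `is_aging_seed`,
#' `is_tsg_seed`) and an edge table (`from`, `to`) stored once per unordered
#' pair with `from < to` lexicographically. Self-loops are never stored.
#'
#' @param nodes character vector of node symbols (canonicalized).
#' @param edges data.frame with character columns `from`, `to`.
#' @param aging_seeds,tsg_seeds optional `gene_set`s (or character vectors)
#'   used to set the node flags.
#' @return an object of class `ppi_network`.
#' @export
ppi_network <- function(nodes = character(),
                        edges = data.frame(from = character(), to = character()),
                        aging_seeds = NULL, tsg_seeds = NULL) {
  nodes <- canonical_symbols(nodes)
  from <- canonical_symbols(edges$from)
  to <- canonical_symbols(edges$to)
  keep <- nzchar(from) & nzchar(to) & from != to
  from <- from[keep]; to <- to[keep]
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  key <- paste(lo, hi, sep = "\r")
  dedup <- !duplicated(key)
  e <- data.frame(from = lo[dedup], to = hi[dedup], stringsAsFactors = FALSE)
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  all_nodes <- sort(unique(c(nodes, e$from, e$to)))
  all_nodes <- all_nodes[nzchar(all_nodes)]
  n <- data.frame(
    gene = all_nodes,
    is_aging_seed = all_nodes %in% as_members(aging_seeds %||% character()),
    is_tsg_seed = all_nodes %in% as_members(tsg_seeds %||% character()),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = n, edges = e), class = "ppi_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network: %d nodes, %d edges; %d aging-seed, %d TSG-seed>\n",
              n_nodes(x), n_edges(x),
              sum(x$nodes$is_aging_seed), sum(x$nodes$is_tsg_seed)))
  invisible(x)
}

#' Number of nodes / edges of a `ppi_network`
#' @param net a `ppi_network`.
#' @return integer count.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Node symbols of a network
#' @param net a `ppi_network`.
#' @return character vector of gene symbols.
#' @export
network_genes <- function(net) net$nodes$gene

#' Build a network from interaction records
#'
#' Duplicate and reversed pairs collapse to a single undirected edge;
#' self-interactions are dropped.
#'
#' @param records data.frame with columns `gene_a`, `gene_b` (e.g. from
#'   [read_interaction_table()]).
#' @param aging_seeds,tsg_seeds optional seed `gene_set`s for node flags.
#' @return a `ppi_network`.
#' @export
build_network <- function(records, aging_seeds = NULL, tsg_seeds = NULL) {
  ppi_network(
    nodes = c(records$gene_a, records$gene_b),
    edges = data.frame(from = records$gene_a, to = records$gene_b,
                       stringsAsFactors = FALSE),
    aging_seeds = aging_seeds, tsg_seeds = tsg_seeds
  )
}

#' Set seed-membership flags on an existing network
#' @param net a `ppi_network`.
#' @param aging_seeds,tsg_seeds `gene_set`s (or character vectors); `NULL`
#'   leaves the corresponding flag untouched.
#' @return the modified `ppi_network`.
#' @export
set_seed_flags <- function(net, aging_seeds = NULL, tsg_seeds = NULL) {
  if (!is.null(aging_seeds)) {
    net$nodes$is_aging_seed <- net$nodes$gene %in% as_members(aging_seeds)
  }
  if (!is.null(tsg_seeds)) {
    net$nodes$is_tsg_seed <- net$nodes$gene %in% as_members(tsg_seeds)
  }
  net
}

#' Merge two networks
#'
#' Node union with OR-combined seed flags, edge union deduplicated.
#' Commutative on (nodes, edges).
#'
#' @param a,b `ppi_network`s.
#' @return the merged `ppi_network`.
#' @export
merge_networks <- function(a, b) {
  out <- ppi_network(
    nodes = c(a$nodes$gene, b$nodes$gene),
    edges = data.frame(from = c(a$edges$from, b$edges$from),
                       to = c(a$edges$to, b$edges$to),
                       stringsAsFactors = FALSE)
  )
  out$nodes$is_aging_seed <- out$nodes$gene %in%
    c(a$nodes$gene[a$nodes$is_aging_seed], b$nodes$gene[b$nodes$is_aging_seed])
  out$nodes$is_tsg_seed <- out$nodes$gene %in%
    c(a$nodes$gene[a$nodes$is_tsg_seed], b$nodes$gene[b$nodes$is_tsg_seed])
  out
}

#' Convert to an igraph object
#'
#' Used internally for shortest-path statistics; vertex order follows the
#' node table, so igraph results map back by name.
#'
#' @param net a `ppi_network`.
#' @return an undirected simple `igraph` graph.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Induced subgraph on a set of genes
#' @param net a `ppi_network`.
#' @param genes character vector of node symbols to keep.
#' @return a `ppi_network` on `intersect(genes, network_genes(net))`.
#' @export
induced_network <- function(net, genes) {
  genes <- canonical_symbols(genes)
  keep_nodes <- net$nodes[net$nodes$gene %in% genes, , drop = FALSE]
  keep_edges <- net$edges[net$edges$from %in% genes & net$edges$to %in% genes,
                          , drop = FALSE]
  out <- ppi_network(keep_nodes$gene, keep_edges)
  out$nodes$is_aging_seed <- out$nodes$gene %in%
    keep_nodes$gene[keep_nodes$is_aging_seed]
  out$nodes$is_tsg_seed <- out$nodes$gene %in%
    keep_nodes$gene[keep_nodes$is_tsg_seed]
  out
}
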