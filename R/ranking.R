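#' Competition ("min") ranking of scores
#'
#' Highest score gets rank 1 (for `direction = "descending"`); equal scores
#' share the smallest applicable rank, and the next distinct score's rank is
#' one plus the number of strictly better items.
#'
#' @param values named numeric vector gene -> score.
#' @param direction `"descending"` (default; large is good) or `"ascending"`.
#' @return named integer vector gene -> rank.
#' @export
rank_scores <- function(values, direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  if (!length(values)) return(stats::setNames(integer(), character()))
  v <- if (direction == "descending") -as.numeric(values) else as.numeric(values)
  stats::setNames(as.integer(rank(v, ties.method = "min")), names(values))
}

#' Combined degree/betweenness rank
#'
#' The prioritization score: elementwise sum of the two rank vectors over an
#' identical gene set. Smaller is better; the global minimum 2 is attained
#' only by a gene ranked first on both criteria.
#'
#' @param rank_de named integer vector of degree ranks.
#' @param rank_be named integer vector of betweenness ranks.
#' @return named integer vector gene -> combined rank.
#' @export
rank_min <- function(rank_de, rank_be) {
  a <- names(rank_de); b <- names(rank_be)
  if (!setequal(a, b)) {
    stop("rank vectors cover different genes; only in first: {",
         paste(setdiff(a, b), collapse = ", "), "}; only in second: {",
         paste(setdiff(b, a), collapse = ", "), "}")
  }
  stats::setNames(as.integer(rank_de[a] + rank_be[a]), a)
}

#' Select and rank candidate genes from the cluster partition
#'
#' The candidate pool is the TSG-connector clusters (clusters 4 and 6 of the
#' partition) minus genes with an already-reported aging role. Degree and
#' betweenness are computed on the *merged* network; ranks are computed
#' within the candidate pool by default (`scope = "pool"`), or over all
#' merged-network nodes and then restricted (`scope = "global"`).
#'
#' @param partition a `cluster_partition` from [partition_clusters()].
#' @param known_aging `gene_set` (or character vector) of genes with a
#'   literature-reported aging role, excluded from the pool.
#' @param merged the merged `ppi_network` the centralities are taken from.
#' @param k number of top candidates to return (default 3).
#' @param scope ranking scope, `"pool"` or `"global"`.
#' @return an object of class `candidate_report`: list with `table` (all
#'   pool genes ordered by `rank_min`, ties lexicographic), `top` (first `k`
#'   rows), `excluded_known` (`gene_set`), `pool_size`.
#' @export
select_candidates <- function(partition, known_aging, merged, k = 3L,
                              scope = c("pool", "global")) {
  scope <- match.arg(scope)
  known <- as_members(known_aging)
  pool46 <- sort(unique(c(partition$clusters[["4"]], partition$clusters[["6"]])))
  pool <- setdiff(pool46, known)
  excluded <- gene_set(intersect(pool46, known), name = "known_aging")
  empty <- data.frame(gene = character(), degree = numeric(),
                      betweenness = numeric(), rank_de = integer(),
                      rank_be = integer(), rank_min = integer(),
                      stringsAsFactors = FALSE)
  if (!length(pool)) {
    warning("candidate pool is empty")
    return(structure(list(table = empty, top = empty,
                          excluded_known = excluded, pool_size = 0L),
                     class = "candidate_report"))
  }
  missing <- setdiff(pool, network_genes(merged))
  if (length(missing)) {
    stop("pool gene(s) not in merged network: ", paste(missing, collapse = ", "))
  }
  deg <- node_degree(merged)
  btw <- node_betweenness(merged)
  if (scope == "pool") {
    rank_de <- rank_scores(deg[pool])
    rank_be <- rank_scores(btw[pool])
  } else {
    rank_de <- rank_scores(deg)[pool]
    rank_be <- rank_scores(btw)[pool]
  }
  rmin <- rank_min(rank_de, rank_be)
  tab <- data.frame(
    gene = pool,
    degree = as.numeric(deg[pool]),
    betweenness = as.numeric(btw[pool]),
    rank_de = as.integer(rank_de[pool]),
    rank_be = as.integer(rank_be[pool]),
    rank_min = as.integer(rmin[pool]),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$rank_min, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, top = utils::head(tab, k),
                 excluded_known = excluded, pool_size = length(pool)),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("<candidate_report: pool of %d genes (%d known-aging excluded)>\n",
              x$pool_size, length(x$excluded_known)))
  print(x$top)
  invisible(x)
}
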