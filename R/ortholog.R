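#' Parameters for the offline orthology stage
#'
#' Defaults follow standard orthology practice for this pipeline: BlastP
#' e-value cutoff 1e-5 and MCL inflation 1.5, plus conventional MCL
#' numerics (expansion 2, prune threshold 1e-5, convergence tolerance 1e-6,
#' at most 100 iterations).
#'
#' @param evalue_cutoff keep similarity records with e-value <= this.
#' @param inflation MCL inflation exponent (> 1).
#' @param expansion MCL expansion power (integer >= 2).
#' @param prune_threshold matrix entries below this are zeroed each
#'   iteration.
#' @param max_iter iteration cap.
#' @param convergence_tol stop when the largest entry change falls below
#'   this.
#' @return an object of class `ortholog_params`.
#' @export
ortholog_params <- function(evalue_cutoff = 1e-5, inflation = 1.5,
                            expansion = 2L, prune_threshold = 1e-5,
                            max_iter = 100L, convergence_tol = 1e-6) {
  stopifnot(evalue_cutoff > 0, inflation > 1, expansion >= 2,
            prune_threshold >= 0, max_iter >= 1, convergence_tol > 0)
  structure(list(evalue_cutoff = evalue_cutoff, inflation = inflation,
                 expansion = as.integer(expansion),
                 prune_threshold = prune_threshold,
                 max_iter = as.integer(max_iter),
                 convergence_tol = convergence_tol),
            class = "ortholog_params")
}

.node_key <- function(species, symbol) paste(species, symbol, sep = "|")

#' Reciprocal best hits from a similarity table
#'
#' After dropping self-hits and records above the e-value cutoff, the best
#' hit of each (query, target species) pair is the record with the lowest
#' e-value (ties: highest bitscore, then lexicographically smallest
#' subject). An edge is kept only when the best-hit relation holds in both
#' directions; its weight is `-log10` of the smaller of the two e-values
#' (e-value 0 is capped at 1e-200 to keep weights finite).
#'
#' @param records similarity data.frame from [read_similarity_table()].
#' @param params an `ortholog_params`.
#' @return data.frame with columns `a`, `b` (node keys `SPECIES|SYMBOL`,
#'   `a < b`) and `weight`, sorted; invariant to input row order.
#' @export
reciprocal_best_hits <- function(records, params = ortholog_params()) {
  empty <- data.frame(a = character(), b = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (length(unique(c(records$query_species, records$subject_species))) < 2L) {
    warning("similarity table spans fewer than two species; no RBH edges")
    return(empty)
  }
  r <- records
  self <- r$query == r$subject & r$query_species == r$subject_species
  r <- r[!self & r$evalue <= params$evalue_cutoff, , drop = FALSE]
  if (!nrow(r)) return(empty)
  r$qkey <- .node_key(r$query_species, r$query)
  r$skey <- .node_key(r$subject_species, r$subject)
  # deterministic best hit per (query node, subject species)
  r <- r[order(r$qkey, r$subject_species, r$evalue, -r$bitscore, r$subject), ,
         drop = FALSE]
  best <- r[!duplicated(paste(r$qkey, r$subject_species, sep = "\r")), ,
            drop = FALSE]
  best_of <- stats::setNames(best$skey,
                             paste(best$qkey, best$subject_species, sep = "\r"))
  best_ev <- stats::setNames(best$evalue, names(best_of))
  fwd_key <- paste(best$qkey, best$subject_species, sep = "\r")
  rev_key <- paste(best$skey, best$query_species, sep = "\r")
  reciprocal <- !is.na(best_of[rev_key]) & best_of[rev_key] == best$qkey
  hits <- best[reciprocal, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  ev_fwd <- hits$evalue
  ev_rev <- unname(best_ev[paste(hits$skey, hits$query_species, sep = "\r")])
  w <- -log10(pmax(pmin(ev_fwd, ev_rev), 1e-200))
  a <- pmin(hits$qkey, hits$skey)
  b <- pmax(hits$qkey, hits$skey)
  out <- data.frame(a = a, b = b, weight = w, stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$a, out$b, sep = "\r")), , drop = FALSE]
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Markov clustering of a weighted edge list
#'
#' Classic MCL: a column-stochastic transition matrix with self-loops (loop
#' weight equal to the node's largest incident edge weight) is iterated by
#' expansion (matrix power), then inflation (entrywise power followed by
#' column renormalization), pruning small entries each round, until the
#' largest entry change drops below the convergence tolerance. Clusters are
#' read off the limit matrix as connected components of its support;
#' attractor systems sharing a column are merged, and a node supported by
#' several systems is assigned to the one containing the lexicographically
#' smallest attractor.
#'
#' @param edges data.frame with columns `a`, `b`, `weight` (e.g. from
#'   [reciprocal_best_hits()]).
#' @param params an `ortholog_params`.
#' @return object of class `mcl_clusters`: list with `clusters` (list of
#'   sorted member vectors, a partition of all nodes), `converged`
#'   (logical), `n_iter`.
#' @export
mcl_cluster <- function(edges, params = ortholog_params()) {
  stopifnot(nrow(edges) > 0)
  nodes <- sort(unique(c(edges$a, edges$b)))
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ia <- match(edges$a, nodes)
  ib <- match(edges$b, nodes)
  for (i in seq_len(nrow(edges))) {
    M[ia[i], ib[i]] <- M[ia[i], ib[i]] + edges$weight[i]
    M[ib[i], ia[i]] <- M[ib[i], ia[i]] + edges$weight[i]
  }
  diag(M) <- apply(M, 1L, max)
  M <- .col_normalize(M)
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iter) {
    iter <- iter + 1L
    prev <- M
    E <- M
    for (p in seq_len(params$expansion - 1L)) E <- E %*% M
    E <- E ^ params$inflation
    E[E < params$prune_threshold] <- 0
    M <- .col_normalize(E)
    if (max(abs(M - prev)) < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", params$max_iter, " iterations")
  }
  structure(list(clusters = .mcl_read_clusters(M, nodes),
                 converged = converged, n_iter = iter),
            class = "mcl_clusters")
}

.col_normalize <- function(M) {
  cs <- colSums(M)
  zero <- cs == 0
  if (any(zero)) {
    # a fully pruned column becomes an absorbing singleton
    M[cbind(which(zero), which(zero))] <- 1
    cs[zero] <- 1
  }
  sweep(M, 2L, cs, "/")
}

.mcl_read_clusters <- function(M, nodes) {
  n <- length(nodes)
  support <- M > 0
  attractors <- which(diag(M) > 0)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- function(i, j) {
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    invisible(NULL)
  }
  # merge attractors that share a column
  for (j in seq_len(n)) {
    att_j <- intersect(which(support[, j]), attractors)
    if (length(att_j) > 1L) for (i in att_j[-1L]) link(att_j[1L], i)
  }
  assign_to <- integer(n)
  for (j in seq_len(n)) {
    att_j <- intersect(which(support[, j]), attractors)
    if (length(att_j)) {
      assign_to[j] <- find(min(att_j))
    } else {
      assign_to[j] <- -j  # no attractor reachable: singleton
    }
  }
  groups <- split(nodes, assign_to)
  out <- lapply(unname(groups), sort)
  out[order(vapply(out, `[[`, "", 1L))]
}

#' @export
print.mcl_clusters <- function(x, ...) {
  cat(sprintf("<mcl_clusters: %d clusters over %d nodes (%sconverged in %d iterations)>\n",
              length(x$clusters), sum(lengths(x$clusters)),
              if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}

#' Ortholog clusters from a similarity table
#'
#' Composition of [reciprocal_best_hits()] and [mcl_cluster()], the offline
#' stand-in for the OrthoMCL orthology stage. Also returns, for each query
#' gene of `from_species`, its co-clustered members of `to_species`.
#'
#' @param records similarity data.frame.
#' @param params an `ortholog_params`.
#' @param from_species,to_species species labels for the returned ortholog
#'   map (default: the two most frequent species in the table, query side
#'   first).
#' @return list with `clusters` (list of sorted `SPECIES|SYMBOL` vectors),
#'   `map` (named list from-symbol -> character vector of to-symbols),
#'   `converged`, `n_clusters`.
#' @export
ortholog_clusters <- function(records, params = ortholog_params(),
                              from_species = NULL, to_species = NULL) {
  edges <- reciprocal_best_hits(records, params)
  if (!nrow(edges)) {
    return(list(clusters = list(), map = stats::setNames(list(), character()),
                converged = TRUE, n_clusters = 0L))
  }
  mcl <- mcl_cluster(edges, params)
  species <- sort(table(c(records$query_species, records$subject_species)),
                  decreasing = TRUE)
  from_species <- toupper(from_species %||% names(species)[1L])
  to_species <- toupper(to_species %||% names(species)[2L])
  map <- list()
  for (cl in mcl$clusters) {
    sp <- sub("\\|.*$", "", cl)
    sym <- sub("^[^|]*\\|", "", cl)
    fr <- sym[sp == from_species]
    to <- sym[sp == to_species]
    for (g in fr) map[[g]] <- sort(to)
  }
  list(clusters = mcl$clusters, map = map[order(names(map))],
       converged = mcl$converged, n_clusters = length(mcl$clusters))
}

#' Write ortholog clusters one per line
#' @param clusters list of character vectors (`SPECIES|SYMBOL` keys).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_cluster_table <- function(clusters, path) {
  writeLines(vapply(clusters, paste, "", collapse = "\t"), path)
  invisible(path)
}
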