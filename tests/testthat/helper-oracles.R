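# Independent oracles used to cross-check the package implementations.
# Everything here is written from the definitions, not by calling the code
# paths under test.

# Random simple undirected graph as a ppi_network (Erdos-Renyi on labels).
random_net <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  if (n < 2) return(ppi_network(nodes))
  pairs <- t(utils::combn(nodes, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  ppi_network(nodes, data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L],
                                stringsAsFactors = FALSE))
}

# Brute-force betweenness: enumerate every shortest path of every unordered
# pair via BFS distances + recursive geodesic enumeration; interior nodes of
# each geodesic get 1/(number of geodesics of that pair).
brute_betweenness <- function(net) {
  nodes <- network_genes(net)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(n_edges(net))) {
    a <- net$edges$from[i]; b <- net$edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  bfs_dist <- function(s) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[[s]] <- 0
    q <- s
    while (length(q)) {
      v <- q[[1L]]; q <- q[-1L]
      for (u in adj[[v]]) {
        if (is.infinite(dist[[u]])) {
          dist[[u]] <- dist[[v]] + 1
          q <- c(q, u)
        }
      }
    }
    dist
  }
  for (si in seq_along(nodes)) {
    s <- nodes[si]
    dist <- bfs_dist(s)
    for (t in nodes[-seq_len(si)]) {
      if (is.infinite(dist[[t]])) next
      paths <- list()
      walk <- function(v, acc) {
        if (v == s) {
          paths[[length(paths) + 1L]] <<- acc
          return(invisible(NULL))
        }
        for (u in adj[[v]]) {
          if (dist[[u]] == dist[[v]] - 1) walk(u, c(u, acc))
        }
      }
      walk(t, character())
      np <- length(paths)
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        for (v in interior) btw[[v]] <- btw[[v]] + 1 / np
      }
    }
  }
  btw
}

# Exhaustive hypergeometric upper tail from binomial coefficients.
hyper_tail <- function(k, K, n, N) {
  j <- seq(k, min(K, n))
  j <- j[(n - j) <= (N - K)]
  if (!length(j)) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Rand index between two partitions (lists of member vectors) of the same
# element set.
rand_index <- function(a, b) {
  lab <- function(cl) {
    el <- unlist(cl, use.names = FALSE)
    stats::setNames(rep(seq_along(cl), lengths(cl)), el)[sort(el)]
  }
  la <- lab(a); lb <- lab(b)
  stopifnot(identical(names(la), names(lb)))
  n <- length(la)
  if (n < 2) return(1)
  idx <- utils::combn(n, 2L)
  mean((la[idx[1L, ]] == la[idx[2L, ]]) == (lb[idx[1L, ]] == lb[idx[2L, ]]))
}

# Plain MCL iteration run blindly to a fixed large iteration count, with
# cluster read-off via components of the limit support. No pruning schedule,
# no convergence test: an independent route to the same fixed point.
oracle_mcl <- function(edges, inflation = 1.5, iters = 200L) {
  nodes <- sort(unique(c(edges$a, edges$b)))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges$a[i], edges$b[i]] <- A[edges$a[i], edges$b[i]] + edges$weight[i]
    A[edges$b[i], edges$a[i]] <- A[edges$b[i], edges$a[i]] + edges$weight[i]
  }
  diag(A) <- apply(A, 1L, max)
  M <- sweep(A, 2L, colSums(A), "/")
  for (it in seq_len(iters)) {
    M <- M %*% M
    M <- M ^ inflation
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2L, cs, "/")
    M[M < 1e-14] <- 0
  }
  supp <- (M > 1e-8) | t(M > 1e-8)
  g <- igraph::graph_from_adjacency_matrix(supp, mode = "undirected",
                                           diag = FALSE)
  unname(lapply(split(nodes, igraph::components(g)$membership), sort))
}

# Wang similarity for two terms of a pure is_a chain root = d0 <- d1 <- ...,
# evaluated from the closed form: S-values along a chain are powers of w.
chain_wang_sim <- function(depth_i, depth_j, w = 0.8) {
  i <- min(depth_i, depth_j); j <- max(depth_i, depth_j)
  common <- sum(w ^ (i - 0:i) + w ^ (j - 0:i))
  sv <- sum(w ^ (i - 0:i)) + sum(w ^ (j - 0:j))
  common / sv
}

# Tiny chain ontology root <- p <- c plus optional extra branches.
chain_ontology <- function(depth, w_ids = sprintf("T%d", 0:depth)) {
  parents <- stats::setNames(lapply(seq_len(depth), function(i) w_ids[i]),
                             w_ids[-1L])
  ontology(w_ids, parents = parents)
}

# Write a minimal interaction TSV with the BioGRID-like columns.
write_tsv_fixture <- function(rows, path) {
  header <- paste("Official Symbol Interactor A",
                  "Official Symbol Interactor B",
                  "Experimental System Type", sep = "\t")
  writeLines(c(header, rows), path)
  path
}
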