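path_net <- function(genes) {
  ppi_network(genes, data.frame(from = genes[-length(genes)], to = genes[-1L],
                                stringsAsFactors = FALSE))
}

test_that("network construction deduplicates pairs and drops loops", {
  net <- build_network(data.frame(gene_a = c("a", "b", "a"),
                                  gene_b = c("b", "a", "b")))
  expect_equal(n_nodes(net), 2L)
  expect_equal(n_edges(net), 1L)

  loop <- build_network(data.frame(gene_a = "a", gene_b = "a"))
  expect_equal(n_nodes(loop), 1L)
  expect_equal(n_edges(loop), 0L)

  path <- build_network(data.frame(gene_a = c("a", "b"), gene_b = c("b", "c")))
  expect_equal(n_nodes(path), 3L)
  expect_equal(n_edges(path), 2L)
})

test_that("degree counts distinct neighbours", {
  star <- ppi_network(edges = data.frame(from = rep("hub", 4),
                                         to = c("l1", "l2", "l3", "l4")))
  deg <- node_degree(star)
  expect_equal(unname(deg["HUB"]), 4)
  expect_true(all(deg[c("L1", "L2", "L3", "L4")] == 1))

  iso <- ppi_network(nodes = c("x", "a", "b"),
                     edges = data.frame(from = "a", to = "b"))
  expect_equal(unname(node_degree(iso)["X"]), 0)

  tri <- ppi_network(edges = data.frame(from = c("a", "b", "c"),
                                        to = c("b", "c", "a")))
  expect_true(all(node_degree(tri) == 2))
})

test_that("degree sum equals twice the edge count on random graphs", {
  for (seed in 1:5) {
    net <- random_net(10, p = 0.4, seed = seed)
    expect_equal(sum(node_degree(net)), 2 * n_edges(net))
  }
})

test_that("betweenness matches closed forms on path, star and cycle", {
  p3 <- path_net(c("a", "b", "c"))
  expect_equal(node_betweenness(p3), c(A = 0, B = 1, C = 0))

  star <- ppi_network(edges = data.frame(from = rep("hub", 4),
                                         to = c("l1", "l2", "l3", "l4")))
  expect_equal(unname(node_betweenness(star)["HUB"]), choose(4, 2))

  cyc <- ppi_network(edges = data.frame(from = c("a", "b", "c", "d"),
                                        to = c("b", "c", "d", "a")))
  expect_true(all(abs(node_betweenness(cyc) - 0.5) < 1e-12))
})

test_that("betweenness equals brute-force geodesic enumeration on random graphs", {
  for (seed in 1:12) {
    net <- random_net(12, p = 0.3, seed = 100 + seed)
    got <- node_betweenness(net)
    want <- brute_betweenness(net)
    expect_equal(got[names(want)], want, tolerance = 1e-10)
    # any degree-1 node lies on no geodesic interior
    deg1 <- names(node_degree(net))[node_degree(net) == 1]
    expect_true(all(got[deg1] == 0))
  }
})

test_that("diameter and mean path length respect components", {
  expect_equal(network_diameter(path_net(c("a", "b", "c", "d"))), 3L)
  tri <- ppi_network(edges = data.frame(from = c("a", "b", "c"),
                                        to = c("b", "c", "a")))
  expect_equal(mean_path_length(tri), 1.0)

  two <- ppi_network(edges = data.frame(from = c("a", "c"), to = c("b", "d")))
  expect_equal(network_diameter(two), 1L)
  expect_equal(mean_path_length(two), 1.0)
  expect_equal(n_components(two), 2L)

  edgeless <- ppi_network(nodes = c("a", "b"))
  expect_equal(network_diameter(edgeless), 0L)
  expect_true(is.na(mean_path_length(edgeless)))
})

test_that("neighbourhoods grow with radius and error on unknown seeds", {
  p5 <- path_net(c("a", "b", "c", "d", "e"))
  expect_setequal(network_genes(neighborhood_network(p5, "c", 1)),
                  c("B", "C", "D"))
  expect_setequal(network_genes(neighborhood_network(p5, "c", 2)),
                  c("A", "B", "C", "D", "E"))
  r0 <- neighborhood_network(p5, "c", 0)
  expect_identical(network_genes(r0), "C")
  expect_equal(n_edges(r0), 0L)
  expect_error(neighborhood_network(p5, "zz", 1), "ZZ")

  # monotone in radius, reaching the seed's component
  net <- random_net(15, p = 0.25, seed = 42)
  seed_gene <- network_genes(net)[1]
  prev <- character()
  for (r in 0:6) {
    cur <- network_genes(neighborhood_network(net, seed_gene, r))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  comp <- igraph::components(as_igraph(net))
  expect_setequal(prev, names(comp$membership)[comp$membership ==
                                                 comp$membership[seed_gene]])
})

test_that("hub selection keeps the top degree quantile with inclusive ties", {
  edges <- data.frame(
    from = c(rep("a", 9), rep("b", 4)),
    to = c("b", sprintf("x%d", 1:8), sprintf("x%d", 1:4)),
    stringsAsFactors = FALSE
  )
  net <- ppi_network(edges = edges)  # 10 nodes: a:9, b:5, rest 1 or 2
  expect_identical(hubs(net, 0.1)$members, "A")
  expect_setequal(hubs(net, 1.0)$members, network_genes(net))

  tie <- ppi_network(edges = data.frame(
    from = c(rep("a", 3), rep("b", 3)),
    to = c("p", "q", "r", "s", "t", "u")
  ))  # a and b tied at degree 3 among 8 nodes
  expect_setequal(hubs(tie, 1 / 8)$members, c("A", "B"))
})

test_that("centrality tables carry consistent ranks", {
  net <- random_net(12, p = 0.35, seed = 77)
  tab <- centrality_table(net)
  expect_equal(tab$rank_min, tab$rank_de + tab$rank_be)
  expect_true(all(tab$rank_min >= 2))
  expect_false(is.unsorted(tab$rank_min))
})
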