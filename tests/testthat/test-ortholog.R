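sim_row <- function(q, s, qs, ss, ev, bs = 500) {
  data.frame(query = q, subject = s, query_species = qs, subject_species = ss,
             evalue = ev, bitscore = bs, stringsAsFactors = FALSE)
}

test_that("reciprocal best hits follow the mutual-best definition", {
  rec <- rbind(sim_row("A1", "B1", "SPA", "SPB", 1e-50),
               sim_row("B1", "A1", "SPB", "SPA", 1e-48),
               sim_row("A1", "B2", "SPA", "SPB", 1e-10),
               sim_row("B2", "A1", "SPB", "SPA", 1e-10))
  edges <- reciprocal_best_hits(rec)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$a, "SPA|A1")
  expect_equal(edges$b, "SPB|B1")
  expect_equal(edges$weight, 50)

  # A1's best is B1 but B1's best is A2: no edge for A1
  rec2 <- rbind(sim_row("A1", "B1", "SPA", "SPB", 1e-40),
                sim_row("B1", "A2", "SPB", "SPA", 1e-60),
                sim_row("B1", "A1", "SPB", "SPA", 1e-40),
                sim_row("A2", "B1", "SPA", "SPB", 1e-60))
  edges2 <- reciprocal_best_hits(rec2)
  expect_equal(nrow(edges2), 1L)
  expect_equal(edges2$a, "SPA|A2")

  # records above the e-value cutoff never form edges
  rec3 <- rbind(sim_row("A1", "B1", "SPA", "SPB", 1e-3),
                sim_row("B1", "A1", "SPB", "SPA", 1e-3))
  expect_equal(nrow(reciprocal_best_hits(rec3)), 0L)

  expect_warning(
    single <- reciprocal_best_hits(sim_row("A1", "A2", "SPA", "SPA", 1e-80)),
    "fewer than two species"
  )
  expect_equal(nrow(single), 0L)
})

test_that("zero e-values are capped and best-hit ties break deterministically", {
  rec <- rbind(sim_row("A1", "B1", "SPA", "SPB", 0),
               sim_row("B1", "A1", "SPB", "SPA", 0))
  expect_equal(reciprocal_best_hits(rec)$weight, 200)

  # equal e-value: higher bitscore wins; then lexicographic subject
  rec2 <- rbind(sim_row("A1", "B2", "SPA", "SPB", 1e-30, bs = 900),
                sim_row("A1", "B1", "SPA", "SPB", 1e-30, bs = 100),
                sim_row("B2", "A1", "SPB", "SPA", 1e-30),
                sim_row("B1", "A1", "SPB", "SPA", 1e-30))
  edges2 <- reciprocal_best_hits(rec2)
  expect_equal(edges2$b, "SPB|B2")
})

triangle_edges <- function(members, w) {
  idx <- utils::combn(members, 2L)
  data.frame(a = pmin(idx[1L, ], idx[2L, ]), b = pmax(idx[1L, ], idx[2L, ]),
             weight = w, stringsAsFactors = FALSE)
}

test_that("MCL keeps disconnected components apart and recovers planted cliques", {
  two_tri <- rbind(triangle_edges(c("a1", "a2", "a3"), 10),
                   triangle_edges(c("b1", "b2", "b3"), 10))
  out <- mcl_cluster(two_tri)
  expect_true(out$converged)
  expect_equal(out$clusters, list(c("a1", "a2", "a3"), c("b1", "b2", "b3")))

  cliques <- lapply(1:3, function(i) sprintf("c%d_%d", i, 1:4))
  strong <- do.call(rbind, lapply(cliques, triangle_edges, w = 50))
  got <- mcl_cluster(strong)$clusters
  expect_equal(got, lapply(cliques, sort))
})

test_that("MCL with weak between-clique edges matches a plain-iteration oracle", {
  cliques <- lapply(1:3, function(i) sprintf("c%d_%d", i, 1:4))
  edges <- do.call(rbind, lapply(cliques, triangle_edges, w = 50))
  bridges <- data.frame(a = c("c1_1", "c2_1"), b = c("c2_2", "c3_2"),
                        weight = 0.5, stringsAsFactors = FALSE)
  edges <- rbind(edges, bridges)
  got <- mcl_cluster(edges, ortholog_params(inflation = 1.5))$clusters
  want <- oracle_mcl(edges, inflation = 1.5)
  expect_equal(got[order(vapply(got, `[[`, "", 1L))],
               want[order(vapply(want, `[[`, "", 1L))])
  expect_equal(length(got), 3L)
})

test_that("ortholog clustering composes RBH and MCL into a species map", {
  # two planted 1:1 ortholog pairs
  rec <- rbind(sim_row("H1", "W1", "HUMAN", "WORM", 1e-80),
               sim_row("W1", "H1", "WORM", "HUMAN", 1e-78),
               sim_row("H2", "W2", "HUMAN", "WORM", 1e-66),
               sim_row("W2", "H2", "WORM", "HUMAN", 1e-60))
  oc <- ortholog_clusters(rec, from_species = "HUMAN", to_species = "WORM")
  expect_equal(oc$n_clusters, 2L)
  expect_true(all(lengths(oc$clusters) == 2L))
  expect_equal(oc$map$H1, "W1")
  expect_equal(oc$map$H2, "W2")

  # 1:2 co-ortholog cluster: all members mutually top hits
  rec12 <- rbind(sim_row("H1", "W1", "HUMAN", "WORM", 1e-90),
                 sim_row("H1", "W2", "HUMAN", "WORM", 1e-85),
                 sim_row("W1", "H1", "WORM", "HUMAN", 1e-90),
                 sim_row("W2", "H1", "WORM", "HUMAN", 1e-85),
                 sim_row("W1", "W2", "WORM", "WORM", 1e-70),
                 sim_row("W2", "W1", "WORM", "WORM", 1e-70))
  oc12 <- ortholog_clusters(rec12, from_species = "HUMAN",
                            to_species = "WORM")
  expect_equal(oc12$n_clusters, 1L)
  expect_equal(oc12$clusters[[1L]],
               c("HUMAN|H1", "WORM|W1", "WORM|W2"))
  expect_equal(oc12$map$H1, c("W1", "W2"))

  # everything above the cutoff: no clusters at all
  faint <- rbind(sim_row("H1", "W1", "HUMAN", "WORM", 1e-2),
                 sim_row("W1", "H1", "WORM", "HUMAN", 1e-2))
  expect_equal(ortholog_clusters(faint)$n_clusters, 0L)
})

test_that("clustering output partitions the surviving nodes and ignores row order", {
  cfg <- synth_config(n_genes = 200, n_aging_seeds = 40, n_tsg_seeds = 30,
                      n_ortholog_clusters = 8, genes_per_cluster = 3,
                      rng_seed = 9)
  sim <- gen_similarity_table(cfg)
  oc <- ortholog_clusters(sim$records, from_species = "HUMAN",
                          to_species = "WORM")
  nodes <- unlist(oc$clusters, use.names = FALSE)
  expect_equal(anyDuplicated(nodes), 0L)
  expect_equal(sort(nodes), sort(unlist(sim$true_clusters)))

  set.seed(1)
  shuffled <- sim$records[sample(nrow(sim$records)), , drop = FALSE]
  oc2 <- ortholog_clusters(shuffled, from_species = "HUMAN",
                           to_species = "WORM")
  expect_identical(oc$clusters, oc2$clusters)
})
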