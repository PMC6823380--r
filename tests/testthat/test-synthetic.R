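small_cfg <- function(...) {
  defaults <- list(n_genes = 400, n_aging_seeds = 80, n_tsg_seeds = 60,
                   n_ortholog_clusters = 5)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

test_that("generators are pure functions of the config", {
  cfg <- synth_config(n_genes = 1000, attachment_m = 3,
                      n_aging_seeds = 100, n_tsg_seeds = 80, rng_seed = 7)
  a <- gen_universe_and_network(cfg)
  b <- gen_universe_and_network(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$lrg$members, b$lrg$members)
  expect_identical(gen_seed_lists(cfg, a$universe),
                   gen_seed_lists(cfg, a$universe))
  expect_identical(gen_similarity_table(cfg)$records,
                   gen_similarity_table(cfg)$records)
})

test_that("LRG labels honour the configured global and hub rates", {
  cfg <- small_cfg(rng_seed = 2)
  uni <- gen_universe_and_network(cfg)
  expect_equal(length(uni$lrg), round(cfg$n_genes * cfg$lrg_fraction))
  expect_true(all(uni$lrg$members %in% uni$universe$members))

  none <- gen_universe_and_network(small_cfg(lrg_fraction = 0, rng_seed = 2))
  expect_length(none$lrg$members, 0L)

  # the hub quota is planted inside the generator's hub stratum
  h <- hubs(uni$network, cfg$hub_top_fraction)$members
  expect_equal(length(intersect(h, uni$lrg$members)),
               round(length(h) * cfg$hub_lrg_fraction))

  # a hub rate the global rate cannot supply is rejected
  expect_error(gen_universe_and_network(
    small_cfg(hub_lrg_fraction = 0.5, rng_seed = 2)), "infeasible")
})

test_that("seed lists honour sizes, overlap and the known-aging subset", {
  cfg <- small_cfg(rng_seed = 11)
  uni <- gen_universe_and_network(cfg)
  seeds <- gen_seed_lists(cfg, uni$universe)
  expect_length(seeds$aging$members, cfg$n_aging_seeds)
  expect_length(seeds$tsg$members, cfg$n_tsg_seeds)
  overlap <- intersect(seeds$aging$members, seeds$tsg$members)
  expect_length(overlap,
                round(cfg$seed_overlap_fraction *
                        min(cfg$n_aging_seeds, cfg$n_tsg_seeds)))
  expect_true(all(seeds$known_aging_tsg$members %in% overlap))

  disjoint <- gen_seed_lists(small_cfg(seed_overlap_fraction = 0,
                                       rng_seed = 11), uni$universe)
  expect_length(intersect(disjoint$aging$members, disjoint$tsg$members), 0L)

  same <- gen_seed_lists(small_cfg(seed_overlap_fraction = 1,
                                   n_aging_seeds = 50, n_tsg_seeds = 50,
                                   rng_seed = 11), uni$universe)
  expect_identical(same$aging$members, same$tsg$members)
})

test_that("the full-scale default seed list sizes are honoured exactly", {
  cfg <- synth_config(rng_seed = 5)
  uni <- gen_universe_and_network(cfg)
  seeds <- gen_seed_lists(cfg, uni$universe)
  expect_length(seeds$aging$members, 741L)
  expect_length(seeds$tsg$members, 464L)
})

test_that("generated ontologies are valid DAGs with planted leaf terms", {
  cfg <- small_cfg(rng_seed = 13)
  universe <- gene_set(sprintf("G%05d", 1:400))
  target <- gene_set(sprintf("G%05d", 1:40))
  go <- gen_ontology_annotations(cfg, universe, target)
  expect_s3_class(go$ontology, "ontology")  # construction validates the DAG
  expect_length(go$ontology$roots, 1L)
  expect_true(all(lengths(go$annotations) > 0))
  expect_true(all(go$planted_terms %in% go$ontology$terms))

  flat <- gen_ontology_annotations(small_cfg(ontology_depth = 1,
                                             rng_seed = 13),
                                   universe, target)
  expect_length(flat$ontology$terms, 1L)
  root <- flat$ontology$terms
  expect_equal(term_similarity(flat$ontology, root, root), 1.0)
})

test_that("generated interaction tables round-trip through the reader", {
  cfg <- small_cfg(rng_seed = 17)
  uni <- gen_universe_and_network(cfg)
  path <- tempfile(fileext = ".tsv")
  write_interaction_table(uni$records, path)
  expect_identical(read_interaction_table(path), uni$records)
})

test_that("similarity tables recover their planted clusters", {
  cfg <- small_cfg(n_ortholog_clusters = 2, genes_per_cluster = 2,
                   rng_seed = 19)
  sim <- gen_similarity_table(cfg)
  oc <- ortholog_clusters(sim$records, from_species = "HUMAN",
                          to_species = "WORM")
  expect_equal(oc$clusters, sim$true_clusters)

  pure <- gen_similarity_table(small_cfg(n_background_pairs = 0,
                                         n_ortholog_clusters = 4,
                                         rng_seed = 19))
  oc2 <- ortholog_clusters(pure$records, from_species = "HUMAN",
                           to_species = "WORM")
  expect_equal(rand_index(oc2$clusters, pure$true_clusters), 1.0)
})

test_that("fixture directories contain every pipeline input plus ground truth", {
  cfg <- small_cfg(rng_seed = 23)
  dir <- tempfile("fixture")
  fx <- generate_fixture_dir(cfg, dir)
  for (f in c("interactions", "aging", "tsg", "known_aging", "lrg",
              "synonyms", "obo", "gaf", "blast", "truth", "config")) {
    expect_true(file.exists(fx[[f]]), info = f)
  }
  truth <- jsonlite::read_json(fx$truth, simplifyVector = TRUE)
  expect_length(truth$aging_seeds, cfg$n_aging_seeds)
  expect_true(all(truth$known_aging %in% truth$tsg_seeds))
  expect_true(truth$enrichment_anchor %in% truth$target_neighborhood)
})
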