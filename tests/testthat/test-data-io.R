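test_that("interaction tables parse, filter by class, and reject bad columns", {
  tsv <- write_tsv_fixture(c("dAf-16\tdaf-2\tphysical",
                             "daf-16\tsir-2.1\tPhysical",
                             "nhr-6\tlet-23\tgenetic"),
                           tempfile(fileext = ".tsv"))
  rec <- read_interaction_table(tsv)
  expect_equal(nrow(rec), 3L)
  expect_setequal(rec$interaction_class, c("physical", "physical", "genetic"))
  expect_equal(rec$gene_a[1], "DAF-16")

  expect_equal(nrow(read_interaction_table(tsv, class_filter = "physical")), 2L)
  expect_equal(nrow(read_interaction_table(tsv, class_filter = "genetic")), 1L)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("Official Symbol Interactor A\tExperimental System Type",
               "a\tphysical"), bad)
  expect_error(read_interaction_table(bad), "Official Symbol Interactor B")

  empty <- write_tsv_fixture(character(), tempfile(fileext = ".tsv"))
  expect_warning(out <- read_interaction_table(empty), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("self-interactions are dropped and BioGRID-style commented headers load", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("# downloaded from somewhere",
               paste("#BioGRID Interaction ID",
                     "Official Symbol Interactor A",
                     "Official Symbol Interactor B",
                     "Experimental System Type", sep = "\t"),
               "103\tdaf-16\tdaf-16\tphysical",
               "104\tdaf-16\tdaf-2\tphysical"), tsv)
  expect_warning(rec <- read_interaction_table(tsv), "self-interaction")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$source_id, "104")
})

test_that("interaction write/read round-trips canonical records", {
  rec <- data.frame(
    gene_a = c("DAF-16", "NHR-6"), gene_b = c("DAF-2", "LET-23"),
    interaction_class = c("physical", "genetic"),
    source_id = c("1", "2"), stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".tsv")
  write_interaction_table(rec, path)
  expect_identical(read_interaction_table(path), rec)
})

test_that("synonym maps resolve aliases, chains, and report collisions", {
  syn <- synonym_map(c("nur77", "Nr4a1"), c("NHR-6", "NHR-6"))
  expect_identical(resolve_synonyms("nur77", syn)$symbols, "NHR-6")

  res <- resolve_synonyms(c("NHR-6", "nur77"), syn)
  expect_identical(res$symbols, "NHR-6")
  expect_equal(res$n_collisions, 1L)

  res2 <- resolve_synonyms("unknownX", syn)
  expect_identical(res2$symbols, "UNKNOWNX")
  expect_equal(res2$n_unresolved, 1L)

  # chains resolve to their fixed point; conflicting aliases and cycles fail
  chain <- synonym_map(c("a", "b"), c("b", "c"))
  expect_identical(resolve_synonyms("a", chain)$symbols, "C")
  expect_error(synonym_map(c("x", "x"), c("A", "B")), "two different")
  expect_error(synonym_map(c("a", "b"), c("b", "a")), "cycl")
})

test_that("synonym tables load from TSV", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("alias\tcanonical", "# comment", "nur77\tNHR-6"), path)
  syn <- read_synonym_table(path)
  expect_identical(resolve_synonyms("NUR77", syn)$symbols, "NHR-6")
})

test_that("XGMML write/read is the identity on nodes, edges and seed flags", {
  for (seed in c(11, 12, 13)) {
    net <- random_net(8, p = 0.4, seed = seed)
    net <- set_seed_flags(net, aging_seeds = network_genes(net)[1:2],
                          tsg_seeds = network_genes(net)[2:4])
    path <- tempfile(fileext = ".xgmml")
    write_xgmml(net, path)
    back <- read_xgmml(path)
    expect_identical(back$nodes, net$nodes)
    expect_identical(back$edges, net$edges)
  }
})

test_that("XGMML reading collapses directed edge pairs and rejects malformed files", {
  raw <- paste0(
    '<graph label="g" directed="1">',
    '<node id="1" label="a"/><node id="2" label="b"/>',
    '<edge source="1" target="2"/><edge source="2" target="1"/>',
    "</graph>"
  )
  path <- tempfile(fileext = ".xgmml")
  writeLines(raw, path)
  net <- read_xgmml(path)
  expect_equal(n_edges(net), 1L)
  expect_equal(net$edges$from, "A")
  expect_equal(net$edges$to, "B")

  dup <- tempfile(fileext = ".xgmml")
  writeLines('<graph><node id="1" label="a"/><node id="2" label="a"/></graph>',
             dup)
  expect_error(read_xgmml(dup), "duplicate")

  orphan <- tempfile(fileext = ".xgmml")
  writeLines(paste0('<graph><node id="1" label="a"/>',
                    '<edge source="1" target="9"/></graph>'), orphan)
  expect_error(read_xgmml(orphan), "unknown node")
})

test_that("OBO terms, is_a closure and annotation loading behave", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:1", "name: root", "",
               "[Term]", "id: GO:2", "name: p", "is_a: GO:1 ! root", "",
               "[Term]", "id: GO:3", "name: c", "is_a: GO:2", "",
               "[Term]", "id: GO:9", "name: gone", "is_obsolete: true"), obo)
  ont <- read_obo(obo)
  expect_setequal(ont$terms, c("GO:1", "GO:2", "GO:3"))

  gaf <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.0", "g1\tGO:3\tIEA", "g2\tGO:77"), gaf)
  expect_warning(ann <- read_gaf(gaf, ont), "unknown terms")
  expect_equal(attr(ann, "n_skipped"), 1L)
  expect_identical(ann$G1, "GO:3")

  # transitive closure reaches the root and is idempotent
  closed <- annotation_closure(ont, ann$G1)
  expect_setequal(closed, c("GO:1", "GO:2", "GO:3"))
  expect_identical(annotation_closure(ont, closed), closed)

  empty_gaf <- tempfile(fileext = ".gaf")
  writeLines("!gaf-version: 2.0", empty_gaf)
  expect_length(read_gaf(empty_gaf, ont), 0L)
})

test_that("cyclic is_a relationships are rejected", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: a", "is_a: b", "",
               "[Term]", "id: b", "is_a: a"), obo)
  expect_error(read_obo(obo), "cyclic")
})
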