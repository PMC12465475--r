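# Concept store: loading, lookups, hierarchy traversal, common ancestors.

write_athena <- function(dir, concepts, rels, strengths = NULL) {
  w <- function(df, f) {
    p <- file.path(dir, f)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    p
  }
  list(concept = w(concepts, "CONCEPT.csv"),
       relationship = w(rels, "CONCEPT_RELATIONSHIP.csv"),
       strength = if (!is.null(strengths)) w(strengths, "DRUG_STRENGTH.csv"))
}

test_that("Athena-dialect tables load with counts preserved and dangling edges rejected", {
  dir <- withr::local_tempdir()
  p <- write_athena(dir, concept_df(1:3), rel_df(c(1, 2), c(2, 3), "RxNorm is a"))
  g <- load_athena_tables(p$concept, p$relationship)
  expect_equal(nrow(g$concepts), 3)
  expect_equal(nrow(g$relationships), 2)

  bad <- write_athena(dir, concept_df(1:2), rel_df(1, 9, "RxNorm is a"))
  expect_error(load_athena_tables(bad$concept, bad$relationship),
               class = "rxnemap_integrity_error")
})

test_that("missing columns and duplicate ids are rejected with informative errors", {
  expect_error(
    concept_graph(concept_df(1:2)[, -3], rel_df()),
    regexp = "vocabulary_id", class = "rxnemap_format_error")
  expect_error(
    concept_graph(concept_df(c(1, 1)), rel_df()),
    class = "rxnemap_integrity_error")
  expect_error(
    concept_graph(concept_df(1, names = ""), rel_df()),
    class = "rxnemap_integrity_error")
})

test_that("loaded store answers name lookup for a full drug-class fixture", {
  w <- example_world()
  hit <- w$graph$concepts[
    w$graph$concepts$concept_name == "Penicillin G 59.4 MG/ML Injectable Solution", ]
  expect_equal(hit$concept_id, 36888637)
  expect_equal(hit$concept_class_id, "Clinical Drug")
})

test_that("related() follows exactly one edge of the requested type", {
  # star: hub 1 with k spokes plus an unrelated edge type
  k <- 7
  g <- concept_graph(concept_df(1:(k + 2)),
                     rel_df(c(rep(1, k), 1), c(2:(k + 1), k + 2),
                            c(rep("RxNorm has ing", k), "Maps to")))
  expect_setequal(related(g, 1, "RxNorm has ing")$concept_id, 2:(k + 1))
  expect_equal(nrow(related(g, 5, "RxNorm has ing")), 0)
  expect_error(related(g, 99, "RxNorm has ing"), class = "rxnemap_lookup_error")

  # brand fixture: Digimerck relates to exactly one ingredient
  w <- example_world()
  rel <- related(w$graph, w$ids[["digimerck"]], "Tradename of")
  expect_equal(rel$concept_name, "digitoxin")
})

test_that("resolve_standard follows maps-to and is reflexive on standard concepts", {
  w <- example_world()
  ctd <- concepts_by_code(w$graph, "7446-20-0", "CTD")
  expect_length(ctd, 1)
  expect_equal(resolve_standard(w$graph, ctd)$concept_name, "zinc sulfate")
  std <- resolve_standard(w$graph, w$ids[["zinc"]])
  expect_equal(std$concept_id, unname(w$ids[["zinc"]]))

  # a non-standard concept with two maps-to edges resolves to both
  g <- concept_graph(
    concept_df(1:3, standard = c(FALSE, TRUE, TRUE)),
    rel_df(c(1, 1), c(2, 3), "Maps to"))
  expect_setequal(resolve_standard(g, 1)$concept_id, c(2, 3))
})

test_that("ancestors is a reflexive transitive closure over hierarchy edges", {
  g <- chain_graph()
  expect_setequal(ancestors(g, 1)$concept_id, 1:4)
  expect_setequal(ancestors(g, 4)$concept_id, 4)
  g2 <- concept_graph(concept_df(1), rel_df())
  expect_equal(ancestors(g2, 1)$concept_id, 1)
  expect_error(ancestors(g, 99), class = "rxnemap_lookup_error")
})

test_that("cycles in hierarchy edges are tolerated with a warning", {
  expect_message(
    g <- concept_graph(concept_df(1:2), rel_df(c(1, 2), c(2, 1), "RxNorm is a")),
    regexp = "cycle")
  expect_setequal(ancestors(g, 1)$concept_id, 1:2)
})

test_that("finest common ancestors: shared clinical drug form, symmetry, identity, disjoint", {
  w <- example_world()
  fca <- finest_common_ancestors(w$graph, 36888637, 44123049)
  expect_equal(fca$concept_id, 40072606)
  expect_equal(fca$concept_name, "penicillin G Injectable Solution")
  swapped <- finest_common_ancestors(w$graph, 44123049, 36888637)
  expect_equal(swapped$concept_id, fca$concept_id)
  self <- finest_common_ancestors(w$graph, 36888637, 36888637)
  expect_equal(self$concept_id, 36888637)
  none <- finest_common_ancestors(w$graph, w$ids[["dabigatran"]],
                                  w$ids[["entrectinib"]])
  expect_equal(nrow(none), 0)
})

test_that("ancestors agrees with the matrix reachability oracle on random DAGs", {
  withr::local_seed(42)
  for (rep in 1:10) {
    n <- sample(20:80, 1)
    edges <- random_dag(n, p = 0.05)
    g <- concept_graph(
      concept_df(1:n, classes = sample(drug_classes_pool(), n, replace = TRUE)),
      edges)
    for (q in sample(n, 5)) {
      expect_equal(sort(ancestors(g, q)$concept_id),
                   oracle_ancestors(1:n, edges, q))
    }
    # monotonicity: for every hierarchy edge x -> y, anc(y) subset of anc(x)
    for (k in utils::head(seq_len(nrow(edges)), 10)) {
      ax <- ancestors(g, edges$concept_id_1[k])$concept_id
      ay <- ancestors(g, edges$concept_id_2[k])$concept_id
      expect_true(all(ay %in% ax))
    }
  }
})

test_that("granularity order is a strict total order with branded classes half a rank above clinical", {
  ranks <- granularity_order()
  expect_false(any(duplicated(ranks)))
  expect_equal(unname(ranks[["Branded Drug"]] - ranks[["Clinical Drug"]]), 0.5)
  expect_equal(unname(ranks[["Quantified Branded Drug Box"]] -
                        ranks[["Quantified Clinical Drug Box"]]), 0.5)
  expect_lt(ranks[["Ingredient"]], ranks[["Clinical Drug"]])
  expect_lt(ranks[["Clinical Drug"]], ranks[["Clinical Drug Box"]])
  expect_lt(ranks[["Clinical Drug Box"]], ranks[["Quantified Clinical Drug"]])
  expect_lt(ranks[["Quantified Clinical Drug Box"]], ranks[["Clinical Pack"]])
  expect_true(is.na(granularity_rank("ATC 5th")))
})

test_that("a graph survives a save/load round trip through the single-file store", {
  w <- example_world()
  p <- withr::local_tempfile(fileext = ".rds")
  save_graph(w$graph, p)
  g2 <- load_graph(p)
  expect_equal(g2$concepts, w$graph$concepts)
  expect_equal(finest_common_ancestors(g2, 36888637, 44123049)$concept_id,
               40072606)
})
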