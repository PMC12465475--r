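# The five ingredient-mapping strategies and their merge semantics.

test_that("ATC strategy maps a monocomponent drug through the lateral link", {
  w <- example_world()
  benzo <- Filter(function(d) d$pzn == "PZNB001", w$drugs)[[1]]
  cand <- map_by_atc(benzo, w$graph)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$target_concept_id, unname(w$ids[["benzocaine"]]))
  expect_equal(cand$strategy, "ATC")
  expect_equal(cand$evidence, "D04AB04")
})

test_that("ATC strategy guards: multiple active ingredients or ambiguous ATC links yield nothing", {
  w <- example_world()
  two_ing <- source_drug("X1", "COMBO",
                         list(source_ingredient("Benzocain"),
                              source_ingredient("Penicillin G")),
                         atc_codes = "D04AB04")
  expect_equal(nrow(map_by_atc(two_ing, w$graph)), 0)

  # an ATC class linked to two ingredients is ambiguous
  g <- concept_graph(
    concept_df(1:3, names = c("atc x", "ing a", "ing b"),
               classes = c("ATC 5th", "Ingredient", "Ingredient"),
               vocab = c("ATC", "RxNorm", "RxNorm"),
               codes = c("X01XX01", "a", "b")),
    rel_df(c(1, 1), c(2, 3), "ATC - RxNorm pr lat"))
  drug <- source_drug("X2", "AMBIG", list(source_ingredient("Stoff")),
                      atc_codes = "X01XX01")
  expect_equal(nrow(map_by_atc(drug, g)), 0)
})

test_that("exact name matching hits normalized ingredient names and deduplicates", {
  w <- example_world()
  ing <- source_ingredient("Olipudase Alfa")
  cand <- map_by_name(ing, w$graph)
  expect_equal(cand$target_concept_id, unname(w$ids[["olipudase"]]))
  expect_equal(cand$strategy, "EXACT_NAME")
  expect_equal(nrow(map_by_name(source_ingredient("Unbekanntium"), w$graph)), 0)
  # several synonyms hitting the same target yield one candidate
  ing2 <- source_ingredient("olipudase alfa", synonyms = "Olipudase-Alfa")
  expect_equal(nrow(map_by_name(ing2, w$graph)), 1)
})

test_that("translation strategy routes German names through the shared-id table", {
  w <- example_world()
  cand <- map_by_translation(source_ingredient("Salicylsäure"), w$links, w$graph)
  expect_equal(cand$target_concept_id, unname(w$ids[["salicylic"]]))
  expect_equal(cand$strategy, "TRANSLATION")
  expect_equal(cand$evidence, "salicylic acid")
  none <- map_by_translation(source_ingredient("Wasser"), w$links, w$graph)
  expect_equal(nrow(none), 0)
})

test_that("CAS strategy bridges via registry number and maps-to resolution", {
  w <- example_world()
  cand <- map_by_cas(source_ingredient("Zinksulfat-Heptahydrat"),
                     w$links, w$graph)
  expect_equal(cand$target_concept_id, unname(w$ids[["zinc"]]))
  expect_equal(cand$strategy, "CAS")
  expect_equal(cand$evidence, "7446-20-0")
  none <- map_by_cas(source_ingredient("Wasser"), w$links, w$graph)
  expect_equal(nrow(none), 0)
})

test_that("brand strategy applies only for single-ingredient drugs with a single-ingredient brand", {
  w <- example_world()
  drug <- Filter(function(d) d$pzn == "PZND001", w$drugs)[[1]]
  cand <- map_by_brand(drug, w$ids[["digimerck"]], w$graph)
  expect_equal(cand$target_concept_id, unname(w$ids[["digitoxin"]]))
  expect_equal(cand$strategy, "BRAND")
  expect_equal(nrow(map_by_brand(drug, NULL, w$graph)), 0)

  # a brand related to two ingredients gives no candidate
  g <- concept_graph(
    concept_df(1:3, names = c("Multibrand", "ing a", "ing b"),
               classes = c("Brand Name", "Ingredient", "Ingredient")),
    rel_df(c(1, 1), c(2, 3), "Tradename of"))
  expect_equal(nrow(map_by_brand(drug, 1, g)), 0)
})

test_that("merge keeps the union without a baseline and respects ATC precedence with one", {
  w <- example_world()
  mk <- function(ing, id, strat) data.frame(
    source_ingredient = ing, target_concept_id = id, strategy = strat,
    evidence = "e", stringsAsFactors = FALSE)
  # no baseline: {X}, {X, Y}, {} -> {X, Y}
  out <- merge_ingredient_candidates(
    list(mk("a", 1L, "EXACT_NAME"),
         rbind(mk("a", 1L, "TRANSLATION"), mk("a", 2L, "TRANSLATION"))),
    atc_baseline = NULL, graph = w$graph)
  expect_setequal(unique(out$target_concept_id), c(1, 2))

  # agreement: baseline X plus name-match X keeps X with both provenances
  base <- mk("a", unname(w$ids[["benzocaine"]]), "ATC")
  out <- merge_ingredient_candidates(
    list(mk("a", unname(w$ids[["benzocaine"]]), "EXACT_NAME")), base, w$graph)
  expect_equal(unique(out$target_concept_id), unname(w$ids[["benzocaine"]]))
  expect_setequal(out$strategy, c("ATC", "EXACT_NAME"))

  # conflict: unrelated CAS candidate dropped with a logged conflict
  expect_message(
    out <- merge_ingredient_candidates(
      list(mk("a", unname(w$ids[["zinc"]]), "CAS")), base, w$graph),
    regexp = "conflicts with ATC baseline")
  expect_equal(out$target_concept_id, unname(w$ids[["benzocaine"]]))
})

test_that("every candidate target carries an ingredient-type class", {
  w <- example_world()
  for (drug in w$drugs) {
    cand <- suppressMessages(map_ingredients(drug, w$links, w$graph))
    if (!nrow(cand)) next
    cls <- w$graph$concepts$concept_class_id[
      match(cand$target_concept_id, w$graph$concepts$concept_id)]
    expect_true(all(cls %in% c("Ingredient", "Precise Ingredient")))
  }
})

test_that("strategy output is monotone in the synonym set", {
  w <- example_world()
  small <- source_ingredient("Zinksulfat-Heptahydrat")
  large <- expand_synonyms(small, extra_synonyms = c("Olipudase Alfa",
                                                     "anything else"))
  for (f in list(function(i) map_by_name(i, w$graph),
                 function(i) map_by_translation(i, w$links, w$graph),
                 function(i) map_by_cas(i, w$links, w$graph))) {
    expect_true(all(f(small)$target_concept_id %in% f(large)$target_concept_id))
  }
})
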