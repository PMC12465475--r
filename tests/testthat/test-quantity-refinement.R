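# Unit normalization, strength matching, hierarchy refinement, finalization.

test_that("quantities normalize to canonical units", {
  expect_equal(normalize_quantity(1, "g"), list(value = 1000, unit = "mg"))
  expect_equal(normalize_quantity(500, "mcg"), list(value = 0.5, unit = "mg"))
  expect_equal(normalize_quantity(2, "l"), list(value = 2000, unit = "mL"))
  expect_equal(normalize_quantity(59.4, "mg/ml"),
               list(value = 59.4, unit = "mg/mL"))
  expect_equal(normalize_quantity(1, "g/l"), list(value = 1, unit = "mg/mL"))
  expect_equal(normalize_quantity(1, "% w/v"), list(value = 10, unit = "mg/mL"))
  expect_equal(normalize_quantity(20, "I.E."), list(value = 20, unit = "UNT"))
  expect_error(normalize_quantity(1, "furlong"), class = "rxnemap_unit_error")
  expect_error(normalize_quantity(1, "%"), class = "rxnemap_unit_error")
})

test_that("unit conversion round-trips are exact", {
  withr::local_seed(21)
  for (i in 1:50) {
    v <- round(stats::runif(1, 0.001, 2000), 4)
    mg <- normalize_quantity(v, "g")
    expect_equal(normalize_quantity(mg$value / 1000, "g")$value, mg$value)
    ml <- normalize_quantity(v, "l")
    expect_equal(normalize_quantity(ml$value, "ml")$value, ml$value)
  }
})

test_that("clinical drug components derive from ingredient plus matching strength", {
  w <- example_world()
  drug <- Filter(function(d) d$pzn == "PZNP001", w$drugs)[[1]]
  cand <- map_ingredients(drug, w$links, w$graph)
  cdc <- derive_cdc(drug, cand, w$graph)
  expect_length(cdc, 1)
  got <- w$graph$concepts[match(cdc[["Penicillin G"]],
                                w$graph$concepts$concept_id), ]
  expect_equal(got$concept_name, "Penicillin G 59.4 MG/ML")

  # incomparable units (UNT component vs mg/ml source) never match
  expect_false(44123049 %in% unlist(cdc))
})

test_that("strength comparison is symmetric and honors the relative tolerance", {
  a <- list(value = 59.4, unit = "mg/mL")
  near <- list(value = 59.4 * (1 + 5e-5), unit = "mg/mL")
  far <- list(value = 59.4 * 1.01, unit = "mg/mL")
  other_unit <- list(value = 59.4, unit = "UNT")
  qm <- rxnemap:::quantity_matches
  expect_true(qm(a, near, tol = 1e-4))
  expect_true(qm(near, a, tol = 1e-4))
  expect_false(qm(a, far, tol = 1e-4))
  expect_false(qm(far, a, tol = 1e-4))
  expect_false(qm(a, other_unit, tol = 1e-4))
})

test_that("brand evidence narrows clinical candidates only when branded concepts exist", {
  w <- example_world()
  # entrectinib CD has a branded counterpart under Rozlytrek
  cd <- unname(w$ids[["ent_cd"]])
  ref <- refine_branded(c(cd, 36888637), w$ids[["rozlytrek"]], w$graph)
  expect_equal(ref$clinical, cd)
  expect_equal(ref$branded, unname(w$ids[["ent_bd"]]))
  # absent brand: identity
  ref2 <- refine_branded(c(cd, 36888637), NULL, w$graph)
  expect_equal(ref2$clinical, sort(c(cd, 36888637)))
  expect_length(ref2$branded, 0)
  # brand present but no branded concept exists: no narrowing
  ref3 <- refine_branded(36888637, w$ids[["rozlytrek"]], w$graph)
  expect_equal(ref3$clinical, 36888637)
  expect_length(ref3$branded, 0)
})

test_that("clinical drugs require exact component cover and a mapped dose form", {
  w <- example_world()
  drug <- Filter(function(d) d$pzn == "PZNP001", w$drugs)[[1]]
  cand <- map_ingredients(drug, w$links, w$graph)
  cdc <- derive_cdc(drug, cand, w$graph)
  forms <- map_doseform_by_registration(drug, w$links)
  expect_equal(forms, unname(w$ids[["form_inj"]]))
  cd <- derive_cd(drug, cdc, forms, w$graph)
  expect_equal(cd, 36888637)
  # wrong dose form: nothing
  expect_length(derive_cd(drug, cdc, w$ids[["form_cap"]], w$graph), 0)
  # empty component set for an ingredient: nothing
  expect_length(derive_cd(drug, list("Penicillin G" = integer()), forms,
                          w$graph), 0)

  # a two-component clinical drug is rejected for a one-ingredient drug
  g <- concept_graph(
    concept_df(1:5, names = c("ing a", "a 1 MG", "b 2 MG", "a+b tablet", "Oral Tablet"),
               classes = c("Ingredient", "Clinical Drug Comp",
                           "Clinical Drug Comp", "Clinical Drug", "Dose Form")),
    rel_df(c(4, 4, 4, 2), c(2, 3, 5, 1),
           c("Consists of", "Consists of", "RxNorm has dose form",
             "RxNorm has ing")))
  one_ing <- source_drug("Y1", "A", list(source_ingredient("a", 1, "mg")))
  expect_length(derive_cd(one_ing, list(a = 2L), 5L, g), 0)
})

test_that("quantified and box candidates require matching size attributes", {
  spec <- fixture_spec(n_ingredients = 6, n_drugs = 12, liquid_fraction = 1,
                       boxed_fraction = 1, branded_fraction = 0,
                       registration_fraction = 1, translation_fraction = 0,
                       cas_fraction = 0, brand_only_fraction = 0,
                       multi_ingredient_fraction = 0,
                       missing_strength_fraction = 0, seed = 5)
  w <- generate_world(spec)
  res <- run_pipeline(w$graph, w$drugs, w$links)
  liquid_classes <- res$rows$target_class[res$rows$target_concept_id > 0]
  expect_true(all(liquid_classes %in% c("Clinical Drug Box",
                                        "Quantified Clinical Drug Box")))

  # box size mismatch yields nothing
  w2 <- example_world()
  expect_length(derive_boxes(w2$ids[["ent_cd"]], 12L, w2$graph), 0)
  expect_equal(derive_boxes(w2$ids[["ent_cd"]], 90L, w2$graph),
               unname(w2$ids[["ent_cdb"]]))
  # absent sizes yield nothing
  expect_length(derive_boxes(w2$ids[["ent_cd"]], NA, w2$graph), 0)
  expect_length(derive_quantified(w2$ids[["ent_cd"]], NULL, w2$graph), 0)
})

test_that("finalize picks the maximal populated target class and supports overrides", {
  w <- example_world()
  cs <- candidate_set("P1", c(w$ids[["penicillin"]], 36888637,
                              w$ids[["pen_cdf"]]), w$graph,
                      evidence = list(ingredient = TRUE, dose_form = TRUE,
                                      strength = TRUE))
  expect_equal(cs$final_class, "Clinical Drug")
  rows <- finalize(cs, w$graph, source_name = "PEN")
  expect_equal(rows$target_concept_id, 36888637)
  expect_equal(rows$match_score, 0.7)

  # ingredient-only baseline
  cs2 <- candidate_set("P2", w$ids[["penicillin"]], w$graph,
                       evidence = list(ingredient = TRUE))
  rows2 <- finalize(cs2, w$graph)
  expect_equal(rows2$target_class, "Ingredient")
  expect_equal(rows2$equivalence_hint, "WIDER")
  expect_equal(rows2$match_score, 0.3)

  # empty candidate set emits a single unmapped row
  cs3 <- candidate_set("P3", integer(), w$graph)
  rows3 <- finalize(cs3, w$graph)
  expect_equal(rows3$target_concept_id, 0L)
  expect_equal(rows3$equivalence_hint, "UNMATCHED")

  # override wins unconditionally
  ov <- data.frame(source_code = "P1", target_concept_id = w$ids[["ent_bdb"]],
                   comment = "pack product", stringsAsFactors = FALSE)
  rows4 <- finalize(cs, w$graph, manual_overrides = ov)
  expect_equal(rows4$target_concept_id, unname(w$ids[["ent_bdb"]]))
  expect_equal(rows4$status, "APPROVED")
})

test_that("adding box or brand evidence never lowers the final class rank", {
  w <- example_world()
  base_ids <- c(w$ids[["entrectinib"]], w$ids[["ent_cd"]])
  base <- candidate_set("P", base_ids, w$graph)
  more <- candidate_set("P", c(base_ids, w$ids[["ent_bd"]], w$ids[["ent_bdb"]]),
                        w$graph)
  expect_gte(granularity_rank(more$final_class),
             granularity_rank(base$final_class))
})
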