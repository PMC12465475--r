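# Common-ancestor comparison of two mapping sets linked by registration.

test_that("registration linking joins shared numbers and expands pairs", {
  left <- data.frame(
    source_code = c("A1", "A2", "A3"),
    eu_registration = c("EU/1/20/0001/001", "EU/1/20/0002/001",
                        "EU/1/20/0003/001"),
    target_concept_id = c(11L, 12L, 13L), stringsAsFactors = FALSE)
  right <- data.frame(
    source_code = c("B1", "B2"),
    eu_registration = c("EU/1/20/0001/001", "EU/1/20/0002/001"),
    target_concept_id = c(21L, 22L), stringsAsFactors = FALSE)
  expect_message(rec <- link_by_registration(left, right),
                 regexp = "one side")
  expect_equal(nrow(rec), 2)
  expect_setequal(rec$left_code, c("A1", "A2"))

  # a range on one side links against the single number on the other
  left2 <- left[1, ]
  left2$eu_registration <- "EU/1/20/0001/001–002"
  rec2 <- suppressMessages(link_by_registration(left2, right))
  expect_equal(rec2$eu_registration, "EU/1/20/0001/001")

  # one-to-many: two left codes on the same registration give two records
  left3 <- rbind(left[1, ], transform(left[1, ], source_code = "A9"))
  rec3 <- suppressMessages(link_by_registration(left3, right))
  expect_equal(nrow(rec3), 2)
})

test_that("comparison finds the boxed clinical ancestor of a branded box vs clinical box pair", {
  w <- example_world()
  rec <- link_by_registration(w$validation$left, w$validation$right)
  out <- lapply(seq_len(nrow(rec)), function(i)
    compare_record(rec[i, , drop = FALSE], w$graph))
  by_reg <- setNames(out, vapply(out, `[[`, "", "eu_registration"))
  roz <- by_reg[["EU/1/20/1460/001"]]
  expect_equal(roz$common_ancestor_class, "Clinical Drug Box")
  expect_equal(roz$common_ancestor_ids, unname(w$ids[["ent_cdb"]]))
  expect_equal(roz$left_class, "Branded Drug Box")
  expect_equal(roz$right_class, "Clinical Drug Box")

  # prodrug vs active moiety: disjoint ancestries, no common ancestor
  dabi <- by_reg[["EU/1/08/0442/001"]]
  expect_equal(dabi$common_ancestor_class, "NONE")
  expect_length(dabi$common_ancestor_ids, 0)
})

test_that("comparison is symmetric under swapping sides and reflexive on identical targets", {
  w <- example_world()
  rec <- link_by_registration(w$validation$left, w$validation$right)
  swapped <- link_by_registration(w$validation$right, w$validation$left)
  for (i in seq_len(nrow(rec))) {
    a <- compare_record(rec[i, , drop = FALSE], w$graph)
    j <- which(swapped$eu_registration == rec$eu_registration[i])
    b <- compare_record(swapped[j, , drop = FALSE], w$graph)
    expect_equal(a$common_ancestor_ids, b$common_ancestor_ids)
    expect_equal(a$common_ancestor_class, b$common_ancestor_class)
  }
  same <- data.frame(source_code = "S", eu_registration = "EU/1/1/1/001",
                     target_concept_id = 36888637L, stringsAsFactors = FALSE)
  rec2 <- link_by_registration(same, transform(same, source_code = "T"))
  out <- compare_record(rec2[1, , drop = FALSE], w$graph)
  expect_equal(out$common_ancestor_ids, 36888637)
  expect_equal(out$common_ancestor_class, "Clinical Drug")
})

test_that("class tallies partition the records and match a hand tally", {
  w <- example_world()
  recs <- validate_mappings(w$validation$left, w$validation$right, w$graph)
  tal <- tally_classes(recs)
  expect_equal(sum(tal$count), length(recs))
  expect_equal(tal$count[tal$ancestor_class == "Clinical Drug Box"], 1L)
  expect_equal(tal$count[tal$ancestor_class == "NONE"], 1L)
  expect_equal(nrow(tally_classes(list())), 0)

  # randomized: aggregate counts equal an independent table() tally
  withr::local_seed(31)
  fake <- lapply(1:200, function(i) list(
    left_class = sample(c("Branded Drug Box", "Clinical Drug"), 1),
    right_class = sample(c("Clinical Drug Box", "Clinical Drug"), 1),
    common_ancestor_class = sample(c("Clinical Drug Box", "Clinical Drug",
                                     "Ingredient", "NONE"), 1)))
  tal2 <- tally_classes(fake)
  expect_equal(sum(tal2$count), 200)
  key <- paste(vapply(fake, `[[`, "", "left_class"),
               vapply(fake, `[[`, "", "common_ancestor_class"),
               vapply(fake, `[[`, "", "right_class"))
  manual <- table(key)
  got <- setNames(tal2$count, paste(tal2$left_class, tal2$ancestor_class,
                                    tal2$right_class))
  expect_equal(got[names(manual)], setNames(as.integer(manual), names(manual)))
})

test_that("validation_side joins mapping rows with source registrations", {
  w <- example_world()
  res <- run_pipeline(w$graph, w$drugs, w$links)
  side <- validation_side(res$rows, w$drugs)
  expect_true("PZNR001" %in% side$source_code)
  expect_false("PZNB001" %in% side$source_code)  # no registration
  expect_equal(side$target_concept_id[side$source_code == "PZNP001"], 36888637)
})
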