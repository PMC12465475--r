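# Dose-form voting, vote thresholding, brand prefix search.

# a graph where anchor ingredient `i` leads to drug concepts carrying the
# requested dose forms, so each source drug retrieves a chosen form set
vote_world <- function(retrieved_sets) {
  n_forms <- max(unlist(retrieved_sets))
  rows <- list(); rels <- list(); next_id <- 1000L
  forms <- seq_len(n_forms)
  rows[[1]] <- concept_df(forms, names = paste("form", forms),
                          classes = "Dose Form")
  anchors <- integer(length(retrieved_sets))
  for (i in seq_along(retrieved_sets)) {
    ing <- next_id; next_id <- next_id + 1L
    rows[[length(rows) + 1]] <- concept_df(ing, names = paste("ing", i))
    anchors[i] <- ing
    for (f in retrieved_sets[[i]]) {
      d <- next_id; next_id <- next_id + 1L
      rows[[length(rows) + 1]] <- concept_df(d, names = paste("drug", d),
                                             classes = "Clinical Drug")
      rels[[length(rels) + 1]] <- rel_df(c(d, d), c(ing, f),
                                         c("RxNorm has ing",
                                           "RxNorm has dose form"))
    }
  }
  list(graph = concept_graph(do.call(rbind, rows), do.call(rbind, rels)),
       anchors = anchors)
}

test_that("votes split equally over retrieved dose forms and accumulate per source form", {
  vw <- vote_world(list(1, c(1, 2), 2))
  drugs <- lapply(1:3, function(i)
    source_drug(paste0("D", i), paste("drug", i),
                list(source_ingredient("x")), dose_form = "Tablette"))
  anchors <- setNames(as.list(vw$anchors), c("D1", "D2", "D3"))

  # single drug retrieving {F} votes 1.0
  t1 <- collect_votes(drugs[1], anchors[1], vw$graph)[[1]]
  expect_equal(unname(t1$votes[["1"]]), 1.0)

  # one drug retrieving {F, G} splits its vote
  t2 <- collect_votes(drugs[2], anchors[2], vw$graph)[[1]]
  expect_equal(unname(t2$votes[["1"]]), 0.5)
  expect_equal(unname(t2$votes[["2"]]), 0.5)

  # three drugs {F}, {F,G}, {G} accumulate to {F: 1.5, G: 1.5}
  t3 <- collect_votes(drugs, anchors, vw$graph)[[1]]
  expect_equal(unname(t3$votes[["1"]]), 1.5)
  expect_equal(unname(t3$votes[["2"]]), 1.5)
  expect_equal(t3$contributing_drugs, 3L)
})

test_that("vote conservation holds on randomized vote scenarios", {
  withr::local_seed(11)
  n <- 300
  sets <- lapply(seq_len(n), function(i) sample(6, sample(3, 1)))
  vw <- vote_world(sets)
  source_forms <- paste0("form-", sample(25, n, replace = TRUE))
  drugs <- lapply(seq_len(n), function(i)
    source_drug(paste0("D", i), "drug", list(source_ingredient("x")),
                dose_form = source_forms[i]))
  anchors <- setNames(as.list(vw$anchors), paste0("D", seq_len(n)))
  tallies <- collect_votes(drugs, anchors, vw$graph)
  expect_equal(sum(vapply(tallies, `[[`, 0L, "contributing_drugs")), n)
  for (t in tallies) {
    expect_equal(sum(t$votes), t$contributing_drugs, tolerance = 1e-9)
    # independent recomputation of this tally from the planted sets
    idx <- which(source_forms == t$source_form)
    manual <- numeric()
    for (i in idx) {
      for (f in as.character(sets[[i]])) {
        manual[f] <- (if (f %in% names(manual)) manual[[f]] else 0) +
          1 / length(sets[[i]])
      }
    }
    expect_equal(t$votes[order(names(t$votes))],
                 manual[order(names(manual))], tolerance = 1e-12)
  }
})

test_that("decide_doseforms applies the alpha threshold deterministically", {
  tally <- function(v) list(source_form = "f", votes = v,
                            contributing_drugs = 0L)
  expect_equal(decide_doseforms(tally(c("1" = 1.5, "2" = 1.5)), 0.5), c(1L, 2L))
  expect_equal(decide_doseforms(tally(c("1" = 3, "2" = 1)), 0.5), 1L)
  expect_equal(decide_doseforms(tally(c("1" = 3, "2" = 1.6)), 0.5), c(1L, 2L))
  expect_equal(decide_doseforms(tally(numeric()), 0.5), integer())
  # never empty on a nonempty tally, even at alpha = 1
  expect_equal(decide_doseforms(tally(c("7" = 0.25)), 1), 7L)
})

test_that("decide_doseforms is scale-invariant", {
  withr::local_seed(12)
  for (i in 1:200) {
    k <- sample(1:6, 1)
    v <- setNames(round(stats::runif(k, 0.01, 5), 3), sample(100, k))
    tally <- list(source_form = "f", votes = v, contributing_drugs = 0L)
    base <- decide_doseforms(tally, 0.5)
    for (c in c(0.1, 3, 1000)) {
      scaled <- list(source_form = "f", votes = v * c, contributing_drugs = 0L)
      expect_equal(decide_doseforms(scaled, 0.5), base)
    }
  }
})

test_that("brand prefix search matches full token sequences, longest first", {
  w <- example_world()
  m <- match_brand("ROZLYTREK HKPS 200MG", w$graph)
  expect_equal(m$brand_concept_id, unname(w$ids[["rozlytrek"]]))
  expect_equal(m$matched_tokens, 1L)
  m2 <- match_brand("Digimerck pico 0.07mg", w$graph)
  expect_equal(m2$brand_concept_id, unname(w$ids[["digimerck"]]))
  expect_null(match_brand("VOLLKOMMEN ANDERS 5MG", w$graph))
})

test_that("tokenization collapses to a stable, case-insensitive form", {
  toks <- tokenize_name("Sab simplex® 69,19 mg/ml")
  expect_equal(toks, tokenize_name(paste(toks, collapse = " ")))
  expect_equal(tokenize_name("ABC-def"), c("abc", "def"))
})

test_that("brand search agrees with the exhaustive prefix scan on random sets", {
  withr::local_seed(13)
  vocab <- c("alpha", "beta", "gamma", "delta", "epsi", "ray", "x", "kola",
             "med", "forte", "plus", "ab")
  for (case in 1:60) {
    n_brands <- sample(3:10, 1)
    brand_names <- vapply(seq_len(n_brands), function(i)
      paste(sample(vocab, sample(2, 1) , replace = TRUE), collapse = " "), "")
    ids <- sample(1000:9999, n_brands)
    g <- concept_graph(
      concept_df(ids, names = brand_names, classes = "Brand Name"),
      rel_df())
    for (probe in 1:5) {
      name <- paste(sample(vocab, sample(1:4, 1), replace = TRUE),
                    collapse = " ")
      got <- match_brand(name, g)
      want <- oracle_brand(name, brand_names, ids)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$brand_concept_id, want$id)
        expect_equal(got$matched_tokens, want$len)
      }
    }
  }
})
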