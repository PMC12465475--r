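# Source terminology loading, synonym expansion, registration normalization.

write_source_fixture <- function(dir) {
  src <- data.frame(
    pzn = paste0("P", 1:5),
    name = c("ALPHA 100MG TABLETTEN", "BETA SAFT", "GAMMA CREME",
             "ROZLYTREK HKPS 200MG", "DELTA SPRAY"),
    registration_status = "registered",
    dose_form = c("Tablette", "Saft", "Creme", "Hartkapsel", "Spray"),
    atc_codes = c("A01AA01", "", "", "", "B02BB02;B02BB03"),
    eu_registration = c("", "", "", "EU/1/20/1460/001", ""),
    ingredients = c("Alphaium|100|mg|1", "Betaium|20|mg/ml|1",
                    "Gammaium|0.5|g|1;Hilfsstoff|||0",
                    "Entrectinib|200|mg|1", "Deltaium|bad|mg|1"),
    stringsAsFactors = FALSE)
  supp <- data.frame(pzn = c("P1", "P4", "P5", "P9"),
                     box_size = c("20", "90", "", ""),
                     total_value = c("", "", "10", ""),
                     total_unit = c("", "", "ml", ""),
                     stringsAsFactors = FALSE)
  sp <- file.path(dir, "source.csv"); kp <- file.path(dir, "supp.csv")
  write.csv(src, sp, row.names = FALSE)
  write.csv(supp, kp, row.names = FALSE)
  list(source = sp, supplement = kp)
}

test_that("source rows join with the supplement; unmatched supplement rows are excluded", {
  dir <- withr::local_tempdir()
  p <- write_source_fixture(dir)
  expect_message(drugs <- load_source(p$source, p$supplement),
                 regexp = "supplement row")
  expect_length(drugs, 5)
  by_pzn <- setNames(drugs, vapply(drugs, `[[`, "", "pzn"))
  expect_equal(by_pzn$P1$box_size, 20L)
  expect_equal(by_pzn$P4$box_size, 90L)
  expect_equal(by_pzn$P5$total_value, 10)
  expect_equal(by_pzn$P5$total_unit, "ml")
  expect_true(is.na(by_pzn$P2$box_size))
  # excipient dropped, active kept
  expect_length(by_pzn$P3$ingredients, 1)
  expect_equal(by_pzn$P3$ingredients[[1]]$raw_name, "Gammaium")
  # EU registration carried on the drug
  expect_equal(by_pzn$P4$eu_registrations, "EU/1/20/1460/001")
  # multiple ATC codes split
  expect_equal(by_pzn$P5$atc_codes, c("B02BB02", "B02BB03"))
})

test_that("malformed strength leaves the strength absent with a warning; duplicate pzn errors", {
  dir <- withr::local_tempdir()
  p <- write_source_fixture(dir)
  expect_message(drugs <- load_source(p$source), regexp = "malformed strength")
  d5 <- Filter(function(d) d$pzn == "P5", drugs)[[1]]
  expect_true(is.na(d5$ingredients[[1]]$strength_value))

  dup <- read.csv(p$source, stringsAsFactors = FALSE)
  dup <- rbind(dup, dup[1, ])
  write.csv(dup, file.path(dir, "dup.csv"), row.names = FALSE)
  expect_error(load_source(file.path(dir, "dup.csv")),
               class = "rxnemap_integrity_error")
})

test_that("loaded source drugs round-trip through write_source", {
  dir <- withr::local_tempdir()
  p <- write_source_fixture(dir)
  drugs <- suppressMessages(load_source(p$source, p$supplement))
  out <- file.path(dir, "roundtrip.csv")
  write_source(drugs, out)
  again <- suppressMessages(load_source(out))
  expect_equal(again, drugs)
})

test_that("synonym expansion applies the stated variation rules", {
  s <- expand_synonyms("alpha lipoic acid")
  expect_true("alpha-lipoic-acid" %in% s)
  expect_true("alpha lipoic acid" %in% s)
  expect_true("olipudase alfa" %in% expand_synonyms("Olipudase Alfa"))
  # umlaut transliteration
  expect_true("salicylsaeure" %in% expand_synonyms("Salicylsäure"))
  # hyphen to space
  expect_true("zinksulfat heptahydrat" %in%
                tolower(expand_synonyms("Zinksulfat-Heptahydrat")))
})

test_that("synonym expansion is idempotent, keeps the original and never yields empty strings", {
  withr::local_seed(7)
  alphabet <- c(letters[1:6], "ä", "ö", "ü", "ß", " ", "-", ".", "(", ")")
  for (i in 1:50) {
    raw <- paste(sample(alphabet, sample(3:12, 1), replace = TRUE),
                 collapse = "")
    if (!nzchar(trimws(raw))) next
    once <- expand_synonyms(raw)
    twice <- expand_synonyms(once)
    expect_identical(twice, once)
    expect_true(all(nzchar(once)))
    expect_true(raw %in% once || !nzchar(trimws(raw)))
  }
  ing <- source_ingredient("Müller-Säure 5%")
  expect_true(ing$raw_name %in% ing$synonyms)
  expect_identical(expand_synonyms(ing)$synonyms, ing$synonyms)
})

test_that("EU registration ranges expand with zero padding preserved", {
  expect_equal(normalize_eu_registration("EU/16/1157/003–004"),
               c("EU/16/1157/003", "EU/16/1157/004"))
  expect_equal(normalize_eu_registration("EU/16/1157/003-005"),
               c("EU/16/1157/003", "EU/16/1157/004", "EU/16/1157/005"))
  expect_equal(normalize_eu_registration("EU/16/1157/003"), "EU/16/1157/003")
  expect_equal(normalize_eu_registration("EU/16/1157/003–003"),
               "EU/16/1157/003")
  expect_message(out <- normalize_eu_registration("EU/16/1157/010–004"),
                 regexp = "unparseable")
  expect_length(out, 0)
  expect_length(normalize_eu_registration(""), 0)
})
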