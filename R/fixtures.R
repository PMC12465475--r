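# Synthetic miniature worlds: an RxN/E-shaped concept graph, a source
# terminology, quantity supplement and cross-link tables, all mutually
# consistent, with planted ground-truth mappings. Everything a pipeline
# stage or the validation comparator needs is generated in code; no
# downloads, no stored binary fixtures.

# ---- incremental world builder -------------------------------------------

world_builder <- function(start_id = 10000L) {
  wb <- new.env(parent = emptyenv())
  wb$next_id <- as.integer(start_id)
  wb$concepts <- list(); wb$rels <- list(); wb$strengths <- list()
  wb$keys <- new.env(parent = emptyenv())
  wb
}

wb_concept <- function(wb, name, class, vocab = "RxNorm Extension",
                       code = NULL, standard = TRUE, id = NULL) {
  id <- as.integer(id %||% {wb$next_id <- wb$next_id + 1L; wb$next_id})
  wb$concepts[[length(wb$concepts) + 1]] <- data.frame(
    concept_id = id, concept_name = name, vocabulary_id = vocab,
    concept_class_id = class, standard_concept = standard,
    concept_code = code %||% paste0("OMOP", id), stringsAsFactors = FALSE)
  id
}

wb_rel <- function(wb, s, t, rel) {
  wb$rels[[length(wb$rels) + 1]] <- data.frame(
    concept_id_1 = as.integer(s), concept_id_2 = as.integer(t),
    relationship_id = rel, stringsAsFactors = FALSE)
  invisible(NULL)
}

wb_strength <- function(wb, drug, ing, amount = NA, amount_unit = NA,
                        num = NA, num_unit = NA, den = NA, den_unit = NA,
                        box = NA) {
  wb$strengths[[length(wb$strengths) + 1]] <- data.frame(
    drug_concept_id = as.integer(drug), ingredient_concept_id = as.integer(ing),
    amount_value = as.numeric(amount), amount_unit = as.character(amount_unit),
    numerator_value = as.numeric(num), numerator_unit = as.character(num_unit),
    denominator_value = as.numeric(den), denominator_unit = as.character(den_unit),
    box_size = as.integer(box), stringsAsFactors = FALSE)
  invisible(NULL)
}

# memoized lookup so shared chain members (components, drug forms) are reused
wb_once <- function(wb, key, builder) {
  hit <- wb$keys[[key]]
  if (!is.null(hit)) return(hit)
  val <- builder()
  wb$keys[[key]] <- val
  val
}

wb_graph <- function(wb, config = graph_config()) {
  concept_graph(do.call(rbind, wb$concepts), do.call(rbind, wb$rels),
                if (length(wb$strengths)) do.call(rbind, wb$strengths) else NULL,
                config)
}

# ---- fixture specification -----------------------------------------------

#' Specification of a synthetic fixture world
#'
#' The knobs control how hard the world is: what share of ingredients is
#' reachable only through translation, only through the CAS bridge or only
#' through a brand; how many drugs are branded, liquid (carrying a total
#' size), boxed, multi-ingredient or missing their strength; and how many
#' carry an EU registration number (and hence can bypass dose-form voting).
#' Generation is fully deterministic given `seed`.
#'
#' @param n_ingredients,n_drugs positive integers
#' @param branded_fraction,liquid_fraction,boxed_fraction,
#'   registration_fraction,translation_fraction,cas_fraction,
#'   brand_only_fraction,multi_ingredient_fraction,
#'   missing_strength_fraction,atc_fraction fractions in `[0, 1]`
#' @param seed integer RNG seed
#' @return list of class `fixture_spec`
#' @export
fixture_spec <- function(n_ingredients = 40, n_drugs = 100,
                         branded_fraction = 0.4, liquid_fraction = 0.25,
                         boxed_fraction = 0.7, registration_fraction = 0.5,
                         translation_fraction = 0.2, cas_fraction = 0.2,
                         brand_only_fraction = 0.1,
                         multi_ingredient_fraction = 0.15,
                         missing_strength_fraction = 0.05,
                         atc_fraction = 0.7, seed = 1) {
  spec <- list(n_ingredients = as.integer(n_ingredients),
               n_drugs = as.integer(n_drugs),
               branded_fraction = branded_fraction,
               liquid_fraction = liquid_fraction,
               boxed_fraction = boxed_fraction,
               registration_fraction = registration_fraction,
               translation_fraction = translation_fraction,
               cas_fraction = cas_fraction,
               brand_only_fraction = brand_only_fraction,
               multi_ingredient_fraction = multi_ingredient_fraction,
               missing_strength_fraction = missing_strength_fraction,
               atc_fraction = atc_fraction,
               seed = as.integer(seed))
  fr <- unlist(spec[grepl("fraction$", names(spec))])
  if (any(fr < 0 | fr > 1)) argument_error("fractions must lie in [0, 1]")
  if (spec$n_ingredients < 1) argument_error("need at least one ingredient")
  if (spec$n_drugs < 1 && any(fr > 0)) {
    argument_error("infeasible spec: drug-level fractions without drugs")
  }
  if (spec$translation_fraction + spec$cas_fraction +
      spec$brand_only_fraction > 1) {
    argument_error("exclusive route fractions exceed 1")
  }
  structure(spec, class = "fixture_spec")
}

SYLLABLES <- c("al", "an", "ar", "be", "bo", "ca", "ce", "ci", "da", "de",
               "do", "en", "er", "fa", "fe", "ga", "ge", "ha", "in", "ka",
               "la", "le", "li", "lo", "ma", "me", "mi", "mo", "na", "ne",
               "ni", "no", "pa", "pe", "pi", "po", "ra", "re", "ri", "ro",
               "sa", "se", "si", "so", "ta", "te", "ti", "to", "ul", "va",
               "ve", "vi", "vo", "xa", "xi", "za", "zo")

name_factory <- function() {
  used <- new.env(parent = emptyenv())
  function(n_syll = 3) {
    repeat {
      nm <- paste(sample(SYLLABLES, n_syll, replace = TRUE), collapse = "")
      if (is.null(used[[nm]])) {
        used[[nm]] <- TRUE
        return(nm)
      }
    }
  }
}

FIXTURE_FORMS <- data.frame(
  rxne = c("Oral Tablet", "Oral Capsule", "Topical Cream",
           "Injectable Solution", "Oral Solution", "Nasal Spray"),
  edqm = c("Tablet", "Capsule, hard", "Cream",
           "Solution for injection", "Oral solution", "Nasal spray"),
  german = c("Tablette", "Hartkapsel", "Creme",
             "Injektionslösung", "Lösung zum Einnehmen",
             "Nasenspray"),
  liquid = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE)

SOLID_STRENGTHS <- c(5, 10, 20, 25, 40, 50, 75, 100, 125, 150, 200, 250,
                     300, 400, 500, 600, 750, 800, 900, 1000)
LIQUID_CONCENTRATIONS <- c(0.5, 1, 2, 2.5, 4, 5, 10, 20, 25, 50)
BOX_SIZES <- c(10, 20, 28, 30, 50, 60, 90, 100)
TOTAL_SIZES <- c(1, 2, 5, 10, 20, 50, 100, 120)

# builds the clinical/branded chain for one drug and returns the concept ids
# per class that exist for it
build_chain <- function(wb, ing_ids, ing_names, strengths, form_id, form_name,
                        brand_id = NULL, brand_name = NULL,
                        total = NULL, box = NULL) {
  cfg <- graph_config()
  n <- length(ing_ids)
  strength_of <- function(drug) {
    for (j in seq_len(n)) {
      s <- strengths[[j]]
      if (identical(s$kind, "amount")) {
        wb_strength(wb, drug, ing_ids[j], amount = s$value, amount_unit = "mg")
      } else {
        wb_strength(wb, drug, ing_ids[j], num = s$value, num_unit = "mg",
                    den_unit = "mL")
      }
    }
  }
  strength_label <- function(j) {
    s <- strengths[[j]]
    if (identical(s$kind, "amount")) paste0(s$value, " MG")
    else paste0(s$value, " MG/ML")
  }
  cdc <- integer(n)
  for (j in seq_len(n)) {
    key <- paste0("cdc|", ing_ids[j], "|", strength_label(j))
    cdc[j] <- wb_once(wb, key, function() {
      id <- wb_concept(wb, paste0(ing_names[j], " ", strength_label(j)),
                       "Clinical Drug Comp")
      wb_rel(wb, id, ing_ids[j], cfg$rel_has_ingredient)
      s <- strengths[[j]]
      if (identical(s$kind, "amount")) {
        wb_strength(wb, id, ing_ids[j], amount = s$value, amount_unit = "mg")
      } else {
        wb_strength(wb, id, ing_ids[j], num = s$value, num_unit = "mg",
                    den_unit = "mL")
      }
      id
    })
  }
  cdf <- integer(n)
  for (j in seq_len(n)) {
    key <- paste0("cdf|", ing_ids[j], "|", form_id)
    cdf[j] <- wb_once(wb, key, function() {
      id <- wb_concept(wb, paste0(ing_names[j], " ", form_name),
                       "Clinical Drug Form")
      wb_rel(wb, id, ing_ids[j], cfg$rel_has_ingredient)
      wb_rel(wb, id, form_id, cfg$rel_has_dose_form)
      id
    })
  }
  cd_name <- paste0(paste0(ing_names, " ", vapply(seq_len(n), strength_label, ""),
                           collapse = " / "), " ", form_name)
  cd_key <- paste0("cd|", paste(cdc, collapse = ","), "|", form_id)
  cd <- wb_once(wb, cd_key, function() {
    id <- wb_concept(wb, cd_name, "Clinical Drug")
    for (j in seq_len(n)) {
      wb_rel(wb, id, cdc[j], cfg$rel_consists_of)
      wb_rel(wb, id, cdf[j], cfg$rel_is_a)
      wb_rel(wb, id, ing_ids[j], cfg$rel_has_ingredient)
    }
    wb_rel(wb, id, form_id, cfg$rel_has_dose_form)
    strength_of(id)
    id
  })
  out <- list(cdc = cdc, cdf = cdf, cd = cd)
  bd <- NULL
  if (!is.null(brand_id)) {
    bdc <- integer(n)
    for (j in seq_len(n)) {
      bdc[j] <- wb_once(wb, paste0("bdc|", cdc[j], "|", brand_id), function() {
        id <- wb_concept(wb, paste0(ing_names[j], " ", strength_label(j),
                                    " [", brand_name, "]"),
                         "Branded Drug Comp")
        wb_rel(wb, id, cdc[j], cfg$rel_tradename_of)
        wb_rel(wb, id, brand_id, cfg$rel_has_brand_name)
        wb_rel(wb, id, ing_ids[j], cfg$rel_has_ingredient)
        id
      })
    }
    bd <- wb_once(wb, paste0("bd|", cd, "|", brand_id), function() {
      id <- wb_concept(wb, paste0(cd_name, " [", brand_name, "]"),
                       "Branded Drug")
      wb_rel(wb, id, cd, cfg$rel_tradename_of)
      wb_rel(wb, id, brand_id, cfg$rel_has_brand_name)
      wb_rel(wb, id, form_id, cfg$rel_has_dose_form)
      for (j in seq_len(n)) wb_rel(wb, id, ing_ids[j], cfg$rel_has_ingredient)
      strength_of(id)
      id
    })
    out$bdc <- bdc
    out$bd <- bd
  }
  qcd <- NULL; qbd <- NULL
  if (!is.null(total)) {
    q_strength <- function(drug) {
      for (j in seq_len(n)) {
        s <- strengths[[j]]
        wb_strength(wb, drug, ing_ids[j], num = s$value * total,
                    num_unit = "mg", den = total, den_unit = "mL")
      }
    }
    qcd <- wb_once(wb, paste0("qcd|", cd, "|", total), function() {
      id <- wb_concept(wb, paste0(total, " ML ", cd_name),
                       "Quantified Clinical Drug")
      wb_rel(wb, id, cd, cfg$rel_quantified_form_of)
      wb_rel(wb, id, form_id, cfg$rel_has_dose_form)
      for (j in seq_len(n)) wb_rel(wb, id, ing_ids[j], cfg$rel_has_ingredient)
      q_strength(id)
      id
    })
    out$qcd <- qcd
    if (!is.null(bd)) {
      qbd <- wb_once(wb, paste0("qbd|", bd, "|", total), function() {
        id <- wb_concept(wb, paste0(total, " ML ", cd_name, " [", brand_name, "]"),
                         "Quantified Branded Drug")
        wb_rel(wb, id, bd, cfg$rel_quantified_form_of)
        wb_rel(wb, id, qcd, cfg$rel_tradename_of)
        wb_rel(wb, id, brand_id, cfg$rel_has_brand_name)
        q_strength(id)
        id
      })
      out$qbd <- qbd
    }
  }
  if (!is.null(box)) {
    box_strength <- function(drug) {
      for (j in seq_len(n)) {
        wb_strength(wb, drug, ing_ids[j], box = box)
      }
    }
    base_c <- qcd %||% cd
    base_c_name <- if (!is.null(qcd)) paste0(total, " ML ", cd_name) else cd_name
    box_class <- if (!is.null(qcd)) "Quantified Clinical Drug Box" else
      "Clinical Drug Box"
    cbox <- wb_once(wb, paste0("cbox|", base_c, "|", box), function() {
      id <- wb_concept(wb, paste0(base_c_name, " Box of ", box), box_class)
      wb_rel(wb, id, base_c, cfg$rel_box_of)
      box_strength(id)
      id
    })
    out$clinical_box <- cbox
    base_b <- qbd %||% bd
    if (!is.null(base_b)) {
      bbox_class <- if (!is.null(qbd)) "Quantified Branded Drug Box" else
        "Branded Drug Box"
      bbox <- wb_once(wb, paste0("bbox|", base_b, "|", box), function() {
        id <- wb_concept(wb, paste0(base_c_name, " [", brand_name,
                                    "] Box of ", box), bbox_class)
        wb_rel(wb, id, base_b, cfg$rel_box_of)
        wb_rel(wb, id, cbox, cfg$rel_tradename_of)
        wb_rel(wb, id, brand_id, cfg$rel_has_brand_name)
        box_strength(id)
        id
      })
      out$branded_box <- bbox
    }
  }
  out
}

#' Generate a synthetic fixture world
#'
#' Builds a self-consistent miniature world: an RxN/E-shaped concept graph
#' with the full concept chain (ingredient, components, drug forms,
#' clinical/branded drugs, quantified forms, boxes) for every synthetic
#' drug, German-style source rows with per-ingredient strengths, a quantity
#' supplement, and translation/CAS/dose-form/registration cross-link tables
#' consistent with the route each ingredient was assigned. The ground truth
#' records the finest planted concept per source code.
#'
#' @param spec a [fixture_spec()]
#' @param dir optional directory: when given, all tables are also written as
#'   CSV/TSV files (Athena dialect for the vocabulary tables) and the
#'   returned list carries their paths
#' @return list with `graph`, `drugs`, `links`, `truth` (data.frame
#'   `source_code`, `expected_class`, `expected_targets` — `;`-joined ids),
#'   and with `paths` when `dir` was given
#' @export
generate_world <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, generate_world_impl(spec, dir))
}

generate_world_impl <- function(spec, dir) {
  cfg <- graph_config()
  wb <- world_builder()
  new_name <- name_factory()

  # dose form concepts
  form_ids <- integer(nrow(FIXTURE_FORMS))
  for (i in seq_len(nrow(FIXTURE_FORMS))) {
    form_ids[i] <- wb_concept(wb, FIXTURE_FORMS$rxne[i], "Dose Form")
  }
  alignment <- data.frame(edqm_term = FIXTURE_FORMS$edqm,
                          rxne_concept_id = form_ids, stringsAsFactors = FALSE)

  # ingredients with exclusive reachability routes
  n_ing <- spec$n_ingredients
  n_tr <- round(spec$translation_fraction * n_ing)
  n_cas <- round(spec$cas_fraction * n_ing)
  n_brand <- round(spec$brand_only_fraction * n_ing)
  routes <- sample(c(rep("TRANSLATION", n_tr), rep("CAS", n_cas),
                     rep("BRAND", n_brand),
                     rep("EXACT", max(0, n_ing - n_tr - n_cas - n_brand))))
  ing <- vector("list", n_ing)
  translations <- list(); cas_tbl <- list()
  for (i in seq_len(n_ing)) {
    english <- paste0(new_name(3), sample(c("ine", "ol", "ide", "ase", "in"), 1))
    id <- wb_concept(wb, english, "Ingredient",
                     vocab = sample(c("RxNorm", "RxNorm Extension"), 1))
    route <- routes[i]
    german <- switch(route,
      EXACT = paste0(toupper(substr(english, 1, 1)),
                     substr(english, 2, nchar(english))),
      TRANSLATION = paste0(toupper(substr(new_name(3), 1, 1)),
                           substr(new_name(2), 1, 90), "säure"),
      CAS = paste0(toupper(substr(new_name(3), 1, 1)), new_name(2), "um"),
      BRAND = paste0(toupper(substr(new_name(3), 1, 1)), new_name(2), "at"))
    if (route == "TRANSLATION") {
      sid <- paste0("SMS", i)
      translations[[length(translations) + 1]] <- data.frame(
        shared_id = sid, language = c("de", "en"), name = c(german, english),
        preferred = c("0", "1"), stringsAsFactors = FALSE)
    }
    if (route == "CAS") {
      cas_no <- sprintf("%04d-%02d-%d", 1000 + i, 10 + (i %% 89), i %% 10)
      cas_tbl[[length(cas_tbl) + 1]] <- data.frame(
        german_name = german, cas_number = cas_no, stringsAsFactors = FALSE)
      ctd <- wb_concept(wb, paste0(english, " (chemical)"), "CTD Chemical",
                        vocab = "CTD", code = cas_no, standard = FALSE)
      wb_rel(wb, ctd, id, cfg$rel_maps_to)
    }
    ing[[i]] <- list(id = id, english = english, german = german,
                     route = route, atc = NULL, uses = 0L)
  }

  # drugs
  source_rows <- list(); supplement <- list(); registration <- list()
  truth <- list()
  multi_pool <- which(routes != "BRAND")
  for (d in seq_len(spec$n_drugs)) {
    multi <- stats::runif(1) < spec$multi_ingredient_fraction &&
      length(multi_pool) >= 2
    idx <- if (multi) sample(multi_pool, 2) else sample(n_ing, 1)
    branded <- stats::runif(1) < spec$branded_fraction ||
      any(routes[idx] == "BRAND")
    if (multi && any(routes[idx] == "BRAND")) {
      idx <- idx[1]  # brand-reachable ingredients stay single-ingredient
      multi <- FALSE
    }
    fi <- sample(nrow(FIXTURE_FORMS), 1)
    liquid <- FIXTURE_FORMS$liquid[fi] && stats::runif(1) < spec$liquid_fraction
    if (any(routes[idx] == "BRAND")) branded <- TRUE
    missing_strength <- !multi && stats::runif(1) < spec$missing_strength_fraction &&
      routes[idx[1]] != "BRAND"
    boxed <- stats::runif(1) < spec$boxed_fraction
    registered <- stats::runif(1) < spec$registration_fraction

    strengths <- lapply(idx, function(j) {
      u <- ing[[j]]$uses
      ing[[j]]$uses <<- u + 1L
      if (liquid) {
        list(kind = "conc",
             value = LIQUID_CONCENTRATIONS[(u %% length(LIQUID_CONCENTRATIONS)) + 1])
      } else {
        list(kind = "amount",
             value = SOLID_STRENGTHS[(u %% length(SOLID_STRENGTHS)) + 1])
      }
    })
    total <- if (liquid) sample(TOTAL_SIZES, 1) else NULL
    box <- if (boxed) sample(BOX_SIZES, 1) else NULL
    brand_id <- NULL; brand_name <- NULL
    if (branded) {
      brand_name <- paste0(toupper(substr(new_name(2), 1, 1)), new_name(2))
      brand_id <- wb_concept(wb, brand_name, "Brand Name")
      for (j in idx) wb_rel(wb, brand_id, ing[[j]]$id, cfg$rel_tradename_of)
    }
    chain <- build_chain(wb, vapply(idx, function(j) ing[[j]]$id, 0L),
                         vapply(idx, function(j) ing[[j]]$english, ""),
                         strengths, form_ids[fi], FIXTURE_FORMS$rxne[fi],
                         brand_id, brand_name, total, box)

    # planted finest target
    truth_entry <- if (missing_strength) {
      list(class = "Ingredient", ids = vapply(idx, function(j) ing[[j]]$id, 0L))
    } else if (!is.null(box) && branded) {
      list(class = if (liquid) "Quantified Branded Drug Box" else
        "Branded Drug Box", ids = chain$branded_box)
    } else if (!is.null(box)) {
      list(class = if (liquid) "Quantified Clinical Drug Box" else
        "Clinical Drug Box", ids = chain$clinical_box)
    } else if (liquid && branded) {
      list(class = "Quantified Branded Drug", ids = chain$qbd)
    } else if (liquid) {
      list(class = "Quantified Clinical Drug", ids = chain$qcd)
    } else if (branded) {
      list(class = "Branded Drug", ids = chain$bd)
    } else {
      list(class = "Clinical Drug", ids = chain$cd)
    }

    pzn <- sprintf("PZN%05d", d)
    truth[[pzn]] <- truth_entry

    # ATC concept and source reference (single-ingredient drugs only)
    atc_codes <- character()
    if (!multi && stats::runif(1) < spec$atc_fraction) {
      j <- idx[1]
      if (is.null(ing[[j]]$atc)) {
        code <- sprintf("A%02dAA%02d", (j %% 90) + 1, j %% 100)
        atc_id <- wb_concept(wb, paste0(ing[[j]]$english, "; systemic"),
                             "ATC 5th", vocab = "ATC", code = code,
                             standard = FALSE)
        wb_rel(wb, atc_id, ing[[j]]$id, cfg$rel_atc_ingredient)
        ing[[j]]$atc <- code
      }
      atc_codes <- ing[[j]]$atc
    }

    eu_reg <- NA_character_
    if (registered) {
      eu_reg <- sprintf("EU/1/%02d/%04d/001", d %% 100, d)
      registration[[length(registration) + 1]] <- data.frame(
        eu_registration = eu_reg, edqm_term = FIXTURE_FORMS$edqm[fi],
        stringsAsFactors = FALSE)
    }

    strength_field <- function(j, k) {
      s <- strengths[[k]]
      if (missing_strength) return(paste0(ing[[j]]$german, "|||1"))
      if (s$kind == "conc") {
        paste0(ing[[j]]$german, "|", s$value, "|mg/ml|1")
      } else if (s$value >= 1000 && stats::runif(1) < 0.3) {
        paste0(ing[[j]]$german, "|", s$value / 1000, "|g|1")
      } else {
        paste0(ing[[j]]$german, "|", s$value, "|mg|1")
      }
    }
    ing_field <- paste(vapply(seq_along(idx), function(k)
      strength_field(idx[k], k), ""), collapse = ";")
    lead <- if (branded) brand_name else toupper(ing[[idx[1]]]$german)
    drug_name <- paste0(lead, " ",
                        if (!missing_strength)
                          paste0(strengths[[1]]$value,
                                 if (liquid) "MG/ML" else "MG", " ") else "",
                        toupper(FIXTURE_FORMS$german[fi]))
    source_rows[[length(source_rows) + 1]] <- data.frame(
      pzn = pzn, name = drug_name, registration_status = "registered",
      dose_form = FIXTURE_FORMS$german[fi],
      atc_codes = paste(atc_codes, collapse = ";"),
      eu_registration = if (is.na(eu_reg)) "" else eu_reg,
      ingredients = ing_field, stringsAsFactors = FALSE)
    supplement[[length(supplement) + 1]] <- data.frame(
      pzn = pzn,
      box_size = if (is.null(box)) "" else as.character(box),
      total_value = if (is.null(total)) "" else as.character(total),
      total_unit = if (is.null(total)) "" else "ml",
      stringsAsFactors = FALSE)
  }

  source_df <- do.call(rbind, source_rows)
  supplement_df <- do.call(rbind, supplement)
  translations_df <- if (length(translations)) do.call(rbind, translations) else
    data.frame(shared_id = character(), language = character(),
               name = character(), preferred = character())
  cas_df <- if (length(cas_tbl)) do.call(rbind, cas_tbl) else
    data.frame(german_name = character(), cas_number = character())
  registration_df <- if (length(registration)) do.call(rbind, registration) else
    data.frame(eu_registration = character(), edqm_term = character())
  truth_df <- data.frame(
    source_code = names(truth),
    expected_class = vapply(truth, `[[`, "", "class"),
    expected_targets = vapply(truth, function(t)
      paste(sort(t$ids), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  rownames(truth_df) <- NULL

  graph <- wb_graph(wb, cfg)
  out <- list(graph = graph,
              truth = truth_df,
              tables = list(source = source_df, supplement = supplement_df,
                            translations = translations_df, cas = cas_df,
                            alignment = alignment,
                            registration = registration_df))
  if (!is.null(dir)) {
    out$paths <- write_world(out, graph, dir)
    out$drugs <- load_source(out$paths$source, out$paths$supplement)
    out$links <- load_crosslinks(out$paths$translations, out$paths$cas,
                                 out$paths$alignment, out$paths$registration,
                                 graph = graph)
  } else {
    tmp <- tempfile("world"); dir.create(tmp)
    paths <- write_world(out, graph, tmp)
    out$drugs <- load_source(paths$source, paths$supplement)
    out$links <- load_crosslinks(paths$translations, paths$cas,
                                 paths$alignment, paths$registration,
                                 graph = graph)
    unlink(tmp, recursive = TRUE)
  }
  out
}

write_world <- function(world, graph, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "", fileEncoding = "UTF-8")
  }
  conc <- graph$concepts
  conc$standard_concept <- ifelse(conc$standard_concept, "S", "")
  write_tsv(conc, p("CONCEPT.csv"))
  write_tsv(graph$relationships, p("CONCEPT_RELATIONSHIP.csv"))
  write_tsv(graph$strengths, p("DRUG_STRENGTH.csv"))
  wcsv <- function(df, path) utils::write.csv(df, path, row.names = FALSE,
                                              na = "", fileEncoding = "UTF-8")
  wcsv(world$tables$source, p("source.csv"))
  wcsv(world$tables$supplement, p("supplement.csv"))
  wcsv(world$tables$translations, p("translations.csv"))
  wcsv(world$tables$cas, p("cas.csv"))
  wcsv(world$tables$alignment, p("doseform_alignment.csv"))
  wcsv(world$tables$registration, p("registration_doseforms.csv"))
  wcsv(world$truth, p("ground_truth.csv"))
  list(concept = p("CONCEPT.csv"), relationship = p("CONCEPT_RELATIONSHIP.csv"),
       strength = p("DRUG_STRENGTH.csv"), source = p("source.csv"),
       supplement = p("supplement.csv"), translations = p("translations.csv"),
       cas = p("cas.csv"), alignment = p("doseform_alignment.csv"),
       registration = p("registration_doseforms.csv"),
       truth = p("ground_truth.csv"))
}

#' Score pipeline output against the planted ground truth
#'
#' A drug is recovered exactly when its final targets equal the planted
#' target set; it is ancestor-consistent when every final target is the
#' planted target or one of the planted target's ancestors (a coarser but
#' compatible mapping).
#'
#' @param result an `rx_mapping` from [run_pipeline()]
#' @param truth ground-truth data.frame from [generate_world()]
#' @param graph the world's `concept_graph`
#' @return list with `n`, `exact_rate`, `ancestor_rate`, and the per-drug
#'   logical vectors `exact`, `ancestor_ok`
#' @export
evaluate_recovery <- function(result, truth, graph) {
  rows <- result$rows
  exact <- logical(nrow(truth)); anc_ok <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    expected <- sort(as.integer(strsplit(truth$expected_targets[i], ";")[[1]]))
    got <- sort(rows$target_concept_id[
      rows$source_code == truth$source_code[i] & rows$target_concept_id > 0])
    exact[i] <- identical(got, expected)
    anc <- sort(unique(unlist(lapply(expected, ancestor_ids, graph = graph),
                              use.names = FALSE)))
    anc_ok[i] <- length(got) > 0 && all(got %in% anc)
  }
  list(n = nrow(truth), exact_rate = mean(exact), ancestor_rate = mean(anc_ok),
       exact = exact, ancestor_ok = anc_ok)
}

# ---- hand-written worked-example bundle ----------------------------------

#' Hand-built example world covering the classic mapping situations
#'
#' A small, fully hand-written vocabulary and source set exercising every
#' mapping route on recognizable drugs: a monocomponent ATC match
#' (Benzocain via D04AB04 to benzocaine), an exact name match (Olipudase
#' Alfa), a translation match (Salicylsäure to salicylic acid), a CAS
#' bridge (Zinksulfat-Heptahydrat via 7446-20-0 to zinc sulfate), a
#' brand-derived ingredient (Digimerck to digitoxin), a penicillin G
#' strength/dose-form chain whose two clinical drugs (59.4 MG/ML vs
#' 1000000 UNT) share one clinical drug form ancestor, an entrectinib
#' branded-box chain resolved from registration, brand and box size, and a
#' prodrug disagreement pair (dabigatran vs dabigatran etexilate) with no
#' common ancestry.
#'
#' @return list with `graph`, `drugs`, `links`, `truth` (named list:
#'   source code -> list(`class`, `ids`)), `validation` (left/right sides
#'   for the common-ancestor comparator) and `ids` (named key concept ids)
#' @export
example_world <- function() {
  cfg <- graph_config()
  wb <- world_builder(start_id = 50000L)

  form_cream <- wb_concept(wb, "Topical Cream", "Dose Form")
  form_inj <- wb_concept(wb, "Injectable Solution", "Dose Form")
  form_cap <- wb_concept(wb, "Oral Capsule", "Dose Form")

  # ingredient pool
  benzocaine <- wb_concept(wb, "benzocaine", "Ingredient", vocab = "RxNorm")
  olipudase <- wb_concept(wb, "olipudase alfa", "Ingredient", vocab = "RxNorm")
  salicylic <- wb_concept(wb, "salicylic acid", "Ingredient", vocab = "RxNorm")
  zinc <- wb_concept(wb, "zinc sulfate", "Ingredient", vocab = "RxNorm")
  digitoxin <- wb_concept(wb, "digitoxin", "Ingredient", vocab = "RxNorm")
  penicillin <- wb_concept(wb, "penicillin G", "Ingredient", vocab = "RxNorm")
  entrectinib <- wb_concept(wb, "entrectinib", "Ingredient", vocab = "RxNorm")
  dabigatran <- wb_concept(wb, "dabigatran", "Ingredient", vocab = "RxNorm")
  dabi_etex <- wb_concept(wb, "dabigatran etexilate", "Ingredient",
                          vocab = "RxNorm")

  # ATC lateral link for the monocomponent benzocaine class
  atc_benzo <- wb_concept(wb, "benzocaine; topical", "ATC 5th",
                          vocab = "ATC", code = "D04AB04", standard = FALSE)
  wb_rel(wb, atc_benzo, benzocaine, cfg$rel_atc_ingredient)

  # CAS bridge concept for zinc sulfate
  ctd_zinc <- wb_concept(wb, "Zinc sulfate (chemical)", "CTD Chemical",
                         vocab = "CTD", code = "7446-20-0", standard = FALSE)
  wb_rel(wb, ctd_zinc, zinc, cfg$rel_maps_to)

  # brand related to exactly one ingredient
  digimerck <- wb_concept(wb, "Digimerck", "Brand Name")
  wb_rel(wb, digimerck, digitoxin, cfg$rel_tradename_of)

  # penicillin G chain: two clinical drugs sharing one clinical drug form
  pen_cdf <- wb_concept(wb, "penicillin G Injectable Solution",
                        "Clinical Drug Form", id = 40072606L)
  wb_rel(wb, pen_cdf, penicillin, cfg$rel_has_ingredient)
  wb_rel(wb, pen_cdf, form_inj, cfg$rel_has_dose_form)
  pen_cdc_mg <- wb_concept(wb, "Penicillin G 59.4 MG/ML", "Clinical Drug Comp")
  wb_rel(wb, pen_cdc_mg, penicillin, cfg$rel_has_ingredient)
  wb_strength(wb, pen_cdc_mg, penicillin, num = 59.4, num_unit = "mg",
              den_unit = "mL")
  pen_cd_mg <- wb_concept(wb, "Penicillin G 59.4 MG/ML Injectable Solution",
                          "Clinical Drug", id = 36888637L)
  wb_rel(wb, pen_cd_mg, pen_cdc_mg, cfg$rel_consists_of)
  wb_rel(wb, pen_cd_mg, pen_cdf, cfg$rel_is_a)
  wb_rel(wb, pen_cd_mg, penicillin, cfg$rel_has_ingredient)
  wb_rel(wb, pen_cd_mg, form_inj, cfg$rel_has_dose_form)
  wb_strength(wb, pen_cd_mg, penicillin, num = 59.4, num_unit = "mg",
              den_unit = "mL")
  pen_cdc_unt <- wb_concept(wb, "Penicillin G 1000000 UNT", "Clinical Drug Comp")
  wb_rel(wb, pen_cdc_unt, penicillin, cfg$rel_has_ingredient)
  wb_strength(wb, pen_cdc_unt, penicillin, amount = 1e6, amount_unit = "UNT")
  pen_cd_unt <- wb_concept(wb, "Penicillin G 1000000 UNT Injectable Solution",
                           "Clinical Drug", id = 44123049L)
  wb_rel(wb, pen_cd_unt, pen_cdc_unt, cfg$rel_consists_of)
  wb_rel(wb, pen_cd_unt, pen_cdf, cfg$rel_is_a)
  wb_rel(wb, pen_cd_unt, penicillin, cfg$rel_has_ingredient)
  wb_rel(wb, pen_cd_unt, form_inj, cfg$rel_has_dose_form)
  wb_strength(wb, pen_cd_unt, penicillin, amount = 1e6, amount_unit = "UNT")

  # entrectinib branded box chain
  rozlytrek <- wb_concept(wb, "Rozlytrek", "Brand Name")
  wb_rel(wb, rozlytrek, entrectinib, cfg$rel_tradename_of)
  ent_cdc <- wb_concept(wb, "entrectinib 200 MG", "Clinical Drug Comp")
  wb_rel(wb, ent_cdc, entrectinib, cfg$rel_has_ingredient)
  wb_strength(wb, ent_cdc, entrectinib, amount = 200, amount_unit = "mg")
  ent_cdf <- wb_concept(wb, "entrectinib Oral Capsule", "Clinical Drug Form")
  wb_rel(wb, ent_cdf, entrectinib, cfg$rel_has_ingredient)
  wb_rel(wb, ent_cdf, form_cap, cfg$rel_has_dose_form)
  ent_cd <- wb_concept(wb, "entrectinib 200 MG Oral Capsule", "Clinical Drug")
  wb_rel(wb, ent_cd, ent_cdc, cfg$rel_consists_of)
  wb_rel(wb, ent_cd, ent_cdf, cfg$rel_is_a)
  wb_rel(wb, ent_cd, entrectinib, cfg$rel_has_ingredient)
  wb_rel(wb, ent_cd, form_cap, cfg$rel_has_dose_form)
  wb_strength(wb, ent_cd, entrectinib, amount = 200, amount_unit = "mg")
  ent_bd <- wb_concept(wb, "entrectinib 200 MG Oral Capsule [Rozlytrek]",
                       "Branded Drug")
  wb_rel(wb, ent_bd, ent_cd, cfg$rel_tradename_of)
  wb_rel(wb, ent_bd, rozlytrek, cfg$rel_has_brand_name)
  wb_rel(wb, ent_bd, entrectinib, cfg$rel_has_ingredient)
  wb_rel(wb, ent_bd, form_cap, cfg$rel_has_dose_form)
  ent_cdb <- wb_concept(wb, "entrectinib 200 MG Oral Capsule Box of 90",
                        "Clinical Drug Box")
  wb_rel(wb, ent_cdb, ent_cd, cfg$rel_box_of)
  wb_strength(wb, ent_cdb, entrectinib, box = 90)
  ent_bdb <- wb_concept(wb,
                        "entrectinib 200 MG Oral Capsule [Rozlytrek] Box of 90",
                        "Branded Drug Box")
  wb_rel(wb, ent_bdb, ent_bd, cfg$rel_box_of)
  wb_rel(wb, ent_bdb, ent_cdb, cfg$rel_tradename_of)
  wb_rel(wb, ent_bdb, rozlytrek, cfg$rel_has_brand_name)
  wb_strength(wb, ent_bdb, entrectinib, box = 90)

  graph <- wb_graph(wb, cfg)

  # cross-link tables
  tmp <- tempfile("example"); dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  wcsv <- function(df, f) {
    p <- file.path(tmp, f)
    utils::write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    p
  }
  tr_p <- wcsv(data.frame(shared_id = c("S1", "S1"),
                          language = c("de", "en"),
                          name = c("Salicylsäure", "salicylic acid"),
                          preferred = c("0", "1")), "translations.csv")
  cas_p <- wcsv(data.frame(german_name = "Zinksulfat-Heptahydrat",
                           cas_number = "7446-20-0"), "cas.csv")
  al_p <- wcsv(data.frame(
    edqm_term = c("Solution for injection", "Capsule, hard"),
    rxne_concept_id = c(form_inj, form_cap)), "doseform_alignment.csv")
  reg_p <- wcsv(data.frame(
    eu_registration = c("EU/1/98/0001/001", "EU/1/20/1460/001"),
    edqm_term = c("Solution for injection", "Capsule, hard")),
    "registration_doseforms.csv")
  links <- load_crosslinks(tr_p, cas_p, al_p, reg_p, graph = graph)

  drugs <- list(
    source_drug("PZNB001", "BENZOCAIN SALBE",
                list(source_ingredient("Benzocain", 50, "mg")),
                dose_form = "Creme", atc_codes = "D04AB04"),
    source_drug("PZNO001", "OLIPUDASE ALFA 20MG PULVER",
                list(source_ingredient("Olipudase Alfa", 20, "mg")),
                dose_form = "Pulver"),
    source_drug("PZNS001", "SALICYLSAEURE LOESUNG 10%",
                list(source_ingredient("Salicylsäure", 100, "mg/ml")),
                dose_form = "Lösung"),
    source_drug("PZNZ001", "ZINKSULFAT AUGENTROPFEN",
                list(source_ingredient("Zinksulfat-Heptahydrat", 2.5, "mg/ml")),
                dose_form = "Augentropfen"),
    source_drug("PZND001", "Digimerck pico 0.07mg Tabletten",
                list(source_ingredient("Digitoxinum", 0.07, "mg")),
                dose_form = "Tablette"),
    source_drug("PZNP001", "PENICILLIN G 59.4MG/ML INJEKTIONSLOESUNG",
                list(source_ingredient("Penicillin G", 59.4, "mg/ml")),
                dose_form = "Injektionslösung",
                eu_registration = "EU/1/98/0001/001"),
    source_drug("PZNR001", "ROZLYTREK HKPS 200MG",
                list(source_ingredient("Entrectinib", 200, "mg")),
                dose_form = "Hartkapsel",
                eu_registration = "EU/1/20/1460/001",
                box_size = 90))

  truth <- list(
    PZNB001 = list(class = "Ingredient", ids = benzocaine),
    PZNO001 = list(class = "Ingredient", ids = olipudase),
    PZNS001 = list(class = "Ingredient", ids = salicylic),
    PZNZ001 = list(class = "Ingredient", ids = zinc),
    PZND001 = list(class = "Ingredient", ids = digitoxin),
    PZNP001 = list(class = "Clinical Drug", ids = 36888637L),
    PZNR001 = list(class = "Branded Drug Box", ids = ent_bdb))

  validation <- list(
    left = data.frame(
      source_code = c("PZNR001", "PZNX001"),
      eu_registration = c("EU/1/20/1460/001", "EU/1/08/0442/001"),
      target_concept_id = c(ent_bdb, dabigatran),
      stringsAsFactors = FALSE),
    right = data.frame(
      source_code = c("TTT100", "TTT200"),
      eu_registration = c("EU/1/20/1460/001", "EU/1/08/0442/001"),
      target_concept_id = c(ent_cdb, dabi_etex),
      stringsAsFactors = FALSE))

  list(graph = graph, drugs = drugs, links = links, truth = truth,
       validation = validation,
       ids = c(benzocaine = benzocaine, olipudase = olipudase,
               salicylic = salicylic, zinc = zinc, digitoxin = digitoxin,
               penicillin = penicillin, entrectinib = entrectinib,
               dabigatran = dabigatran, dabigatran_etexilate = dabi_etex,
               digimerck = digimerck, rozlytrek = rozlytrek,
               pen_cdf = pen_cdf, pen_cd_mg = pen_cd_mg,
               pen_cd_unt = pen_cd_unt, ent_cd = ent_cd, ent_bd = ent_bd,
               ent_cdb = ent_cdb, ent_bdb = ent_bdb,
               form_inj = form_inj, form_cap = form_cap))
}
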