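# Ingredient mapping strategies. Each strategy emits candidate target
# concepts of an ingredient-type class with provenance (the ATC code, matched
# synonym, CAS number or brand that produced it); candidates are merged by
# union, with mappings given by the ATC relation respected as the baseline
# that other strategies may only refine.

empty_candidates <- function() {
  data.frame(source_ingredient = character(), target_concept_id = integer(),
             strategy = character(), evidence = character(),
             stringsAsFactors = FALSE)
}

candidate_rows <- function(source_ingredient, target_concept_id, strategy,
                           evidence) {
  if (!length(target_concept_id)) return(empty_candidates())
  data.frame(source_ingredient = source_ingredient,
             target_concept_id = as.integer(target_concept_id),
             strategy = strategy, evidence = evidence,
             stringsAsFactors = FALSE)
}

ingredient_class_ids <- function(graph, ids) {
  ids[concept_class_of(graph, ids) %in% INGREDIENT_CLASSES]
}

# precise ingredients are additionally expanded to their base ingredient
expand_precise <- function(graph, ids) {
  precise <- ids[concept_class_of(graph, ids) == "Precise Ingredient"]
  extra <- unlist(lapply(precise, function(p)
    related_ids(graph, p, graph$config$rel_form_of)), use.names = FALSE)
  sort(unique(c(ids, ingredient_class_ids(graph, extra))))
}

#' Map a drug's ingredient via its ATC code(s)
#'
#' Applicable only when the drug has exactly one active ingredient; each of
#' its ATC codes is followed over the lateral ATC-to-ingredient relationship
#' and contributes a candidate only when that code links to exactly one
#' ingredient concept (monocomponent ATC class). A precise-ingredient target
#' is additionally expanded to its base ingredient.
#'
#' @param drug a [source_drug()]
#' @param graph a `concept_graph` containing ATC concepts and the lateral
#'   relationship
#' @return candidate data.frame (columns `source_ingredient`,
#'   `target_concept_id`, `strategy`, `evidence`)
#' @export
map_by_atc <- function(drug, graph) {
  actives <- active_ingredients(drug)
  if (length(actives) != 1 || !length(drug$atc_codes)) return(empty_candidates())
  out <- empty_candidates()
  for (code in drug$atc_codes) {
    atc_ids <- concepts_by_code(graph, code, vocabulary_id = "ATC")
    targets <- unlist(lapply(atc_ids, function(a)
      related_ids(graph, a, graph$config$rel_atc_ingredient)), use.names = FALSE)
    targets <- ingredient_class_ids(graph, unique(targets))
    if (length(targets) != 1) next
    out <- rbind(out, candidate_rows(actives[[1]]$raw_name,
                                     expand_precise(graph, targets),
                                     "ATC", code))
  }
  unique(out)
}

#' Map an ingredient by exact (normalized) name match
#'
#' Compares every synonym of the ingredient against the normalized names of
#' the graph's ingredient-class concepts.
#'
#' @param ing a [source_ingredient()]
#' @param graph a `concept_graph`
#' @return candidate data.frame; one row per distinct target, with the
#'   matching synonym as evidence
#' @export
map_by_name <- function(ing, graph) {
  hits <- match_ingredient_names(graph, ing$synonyms)
  if (!nrow(hits)) return(empty_candidates())
  hits <- hits[!duplicated(hits$target_concept_id), , drop = FALSE]
  candidate_rows(ing$raw_name, hits$target_concept_id, "EXACT_NAME",
                 hits$evidence)
}

match_ingredient_names <- function(graph, names) {
  keys <- norm_name(names)
  keep <- nzchar(keys)
  names <- names[keep]; keys <- keys[keep]
  res <- lapply(seq_along(keys), function(i) {
    ids <- graph$ing_name_index[[keys[i]]]
    if (is.null(ids)) return(NULL)
    data.frame(target_concept_id = ids, evidence = names[i],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) data.frame(target_concept_id = integer(),
                               evidence = character(),
                               stringsAsFactors = FALSE)
  else res
}

#' Map an ingredient via translation to English
#'
#' Every synonym is translated through the substance translation table; the
#' translated forms are treated as synonyms and matched against the graph's
#' ingredient names. Evidence records the translated form used.
#'
#' @param ing a [source_ingredient()]
#' @param links a `crosslinks`
#' @param graph a `concept_graph`
#' @return candidate data.frame
#' @export
map_by_translation <- function(ing, links, graph) {
  translated <- unique(unlist(lapply(ing$synonyms, translate, links = links),
                              use.names = FALSE))
  if (!length(translated)) return(empty_candidates())
  hits <- match_ingredient_names(graph, translated)
  if (!nrow(hits)) return(empty_candidates())
  hits <- hits[!duplicated(hits$target_concept_id), , drop = FALSE]
  candidate_rows(ing$raw_name, hits$target_concept_id, "TRANSLATION",
                 hits$evidence)
}

#' Map an ingredient via its CAS registry number
#'
#' Synonyms are looked up in the German-substance-name-to-CAS table; each CAS
#' number is matched against concept codes of the (non-standard) chemical
#' bridge vocabulary and resolved over maps-to edges to standard
#' ingredient-class concepts.
#'
#' @param ing a [source_ingredient()]
#' @param links a `crosslinks`
#' @param graph a `concept_graph`
#' @return candidate data.frame with the CAS number as evidence
#' @export
map_by_cas <- function(ing, links, graph) {
  cas_numbers <- unique(unlist(lapply(ing$synonyms, cas_lookup, links = links),
                               use.names = FALSE))
  if (!length(cas_numbers)) return(empty_candidates())
  out <- empty_candidates()
  for (cas in cas_numbers) {
    bridge <- concepts_by_code(graph, cas)
    std <- unlist(lapply(bridge, function(b) resolve_standard_ids(graph, b)),
                  use.names = FALSE)
    std <- ingredient_class_ids(graph, unique(std))
    out <- rbind(out, candidate_rows(ing$raw_name, std, "CAS", cas))
  }
  out <- out[!duplicated(out[c("source_ingredient", "target_concept_id")]), ,
             drop = FALSE]
  out
}

#' Map a drug's ingredient via its matched brand
#'
#' Applicable only when the drug has exactly one active ingredient and the
#' matched brand-name concept is the tradename of exactly one ingredient
#' concept; that ingredient becomes the candidate.
#'
#' @param drug a [source_drug()]
#' @param brand_concept_id matched brand concept id, or `NULL`/`NA` when no
#'   brand was matched
#' @param graph a `concept_graph`
#' @return candidate data.frame with the brand name as evidence
#' @export
map_by_brand <- function(drug, brand_concept_id, graph) {
  if (is.null(brand_concept_id) || is.na(brand_concept_id))
    return(empty_candidates())
  actives <- active_ingredients(drug)
  if (length(actives) != 1) return(empty_candidates())
  targets <- ingredient_class_ids(
    graph, related_ids(graph, brand_concept_id, graph$config$rel_tradename_of))
  if (length(targets) != 1) return(empty_candidates())
  candidate_rows(actives[[1]]$raw_name, targets, "BRAND",
                 concept_name_of(graph, brand_concept_id))
}

#' Merge per-strategy ingredient candidates under ATC precedence
#'
#' Takes the union of all strategies' candidate rows. When the ATC baseline
#' is nonempty for a source ingredient, candidates from other strategies
#' that contradict it (a different target that is not a hierarchy descendant
#' of any baseline target) are dropped, and the conflict is logged rather
#' than silently discarded.
#'
#' @param per_strategy list of candidate data.frames
#' @param atc_baseline candidate data.frame from [map_by_atc()]
#' @param graph a `concept_graph`
#' @return merged candidate data.frame, one row per
#'   (source ingredient, target, strategy)
#' @export
merge_ingredient_candidates <- function(per_strategy, atc_baseline = NULL,
                                        graph = NULL) {
  all_rows <- do.call(rbind, c(list(empty_candidates()), per_strategy,
                               if (!is.null(atc_baseline)) list(atc_baseline)))
  all_rows <- all_rows[!duplicated(all_rows[c("source_ingredient",
                                              "target_concept_id",
                                              "strategy")]), , drop = FALSE]
  if (is.null(atc_baseline) || !nrow(atc_baseline)) {
    rownames(all_rows) <- NULL
    return(all_rows)
  }
  keep <- rep(TRUE, nrow(all_rows))
  for (ing in unique(atc_baseline$source_ingredient)) {
    base_targets <- atc_baseline$target_concept_id[
      atc_baseline$source_ingredient == ing]
    rows <- which(all_rows$source_ingredient == ing &
                  all_rows$strategy != "ATC")
    for (r in rows) {
      tgt <- all_rows$target_concept_id[r]
      if (tgt %in% base_targets) next
      refines <- !is.null(graph) &&
        length(intersect(base_targets, ancestor_ids(graph, tgt))) > 0
      if (!refines) {
        keep[r] <- FALSE
        rx_log("warn", "ingredient '", ing, "': ", all_rows$strategy[r],
               " candidate ", tgt, " conflicts with ATC baseline {",
               paste(base_targets, collapse = ", "), "}; dropped")
      }
    }
  }
  out <- all_rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run all ingredient-mapping strategies for one drug
#'
#' Attempts the five strategies in order (ATC, exact name, translation, CAS,
#' brand) for every active ingredient and merges the results under ATC
#' precedence.
#'
#' @param drug a [source_drug()]
#' @param links a `crosslinks`
#' @param graph a `concept_graph`
#' @param brand_concept_id optional matched brand concept id
#' @return merged candidate data.frame
#' @export
map_ingredients <- function(drug, links, graph, brand_concept_id = NULL) {
  baseline <- map_by_atc(drug, graph)
  per <- list()
  for (ing in active_ingredients(drug)) {
    per[[length(per) + 1]] <- map_by_name(ing, graph)
    per[[length(per) + 1]] <- map_by_translation(ing, links, graph)
    per[[length(per) + 1]] <- map_by_cas(ing, links, graph)
  }
  per[[length(per) + 1]] <- map_by_brand(drug, brand_concept_id, graph)
  merge_ingredient_candidates(per, baseline, graph)
}
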