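# Configuration objects: relationship vocabulary, concept-class granularity,
# unit conversion table, pipeline tuning parameters.

#' Relationship and hierarchy configuration for a concept graph
#'
#' Names the `relationship_id` values the graph operations rely on and the
#' subset treated as hierarchy ("upward") links when computing ancestors.
#' Defaults follow the relationship naming of the OMOP drug vocabularies; all
#' values can be overridden to adapt to a differently-labelled vocabulary
#' dump.
#'
#' The hierarchy links point from the more specific concept to the more
#' general one: a clinical drug *is a* clinical drug form, *consists of* its
#' components, a branded concept is a *tradename of* its clinical
#' counterpart, quantified and boxed concepts link down to their unquantified
#' and unboxed bases, and drug concepts link to their ingredients.
#'
#' @param rel_maps_to non-standard to standard mapping relationship
#' @param rel_atc_ingredient lateral link from a monocomponent ATC class
#'   concept to its equivalent ingredient concept
#' @param rel_form_of link from a precise ingredient to its base ingredient
#' @param rel_is_a generic is-a link (clinical drug to clinical drug form)
#' @param rel_consists_of clinical drug to clinical drug component
#' @param rel_tradename_of branded concept to clinical counterpart (also
#'   brand name concept to ingredient)
#' @param rel_quantified_form_of quantified concept to unquantified base
#' @param rel_box_of box concept to unboxed base
#' @param rel_marketed_form_of marketed product to its base concept
#' @param rel_has_ingredient drug concept to ingredient
#' @param rel_has_dose_form drug concept to dose form (attribute link, not
#'   part of the hierarchy)
#' @param rel_has_brand_name branded drug concept to brand name (attribute
#'   link)
#' @param hierarchy_rels character vector of relationship ids whose edges are
#'   followed by [ancestors()]
#' @return a named list of class `rx_graph_config`
#' @export
graph_config <- function(rel_maps_to = "Maps to",
                         rel_atc_ingredient = "ATC - RxNorm pr lat",
                         rel_form_of = "Form of",
                         rel_is_a = "RxNorm is a",
                         rel_consists_of = "Consists of",
                         rel_tradename_of = "Tradename of",
                         rel_quantified_form_of = "Quantified form of",
                         rel_box_of = "Box of",
                         rel_marketed_form_of = "Marketed form of",
                         rel_has_ingredient = "RxNorm has ing",
                         rel_has_dose_form = "RxNorm has dose form",
                         rel_has_brand_name = "Has brand name",
                         hierarchy_rels = NULL) {
  cfg <- list(
    rel_maps_to = rel_maps_to,
    rel_atc_ingredient = rel_atc_ingredient,
    rel_form_of = rel_form_of,
    rel_is_a = rel_is_a,
    rel_consists_of = rel_consists_of,
    rel_tradename_of = rel_tradename_of,
    rel_quantified_form_of = rel_quantified_form_of,
    rel_box_of = rel_box_of,
    rel_marketed_form_of = rel_marketed_form_of,
    rel_has_ingredient = rel_has_ingredient,
    rel_has_dose_form = rel_has_dose_form,
    rel_has_brand_name = rel_has_brand_name
  )
  cfg$hierarchy_rels <- hierarchy_rels %||% c(
    rel_is_a, rel_consists_of, rel_tradename_of, rel_quantified_form_of,
    rel_box_of, rel_marketed_form_of, rel_has_ingredient
  )
  structure(cfg, class = "rx_graph_config")
}

# Concept classes carrying ingredient-level semantics.
INGREDIENT_CLASSES <- c("Ingredient", "Precise Ingredient")

#' Granularity order of drug concept classes
#'
#' Total order over the drug concept classes by increasing information
#' content: an ingredient conveys the least, quantified boxed and pack
#' concepts the most. Each branded class ranks immediately above its
#' clinical counterpart (clinical rank + 0.5), so ties between a clinical
#' concept and its branded form resolve towards the branded one.
#'
#' @return named numeric vector, names are concept classes, values are ranks
#' @export
granularity_order <- function() {
  c("Ingredient" = 1,
    "Precise Ingredient" = 1.25,
    "Dose Form" = 2,
    "Brand Name" = 3,
    "Clinical Drug Comp" = 4, "Branded Drug Comp" = 4.5,
    "Clinical Drug Form" = 5, "Branded Drug Form" = 5.5,
    "Clinical Drug" = 6, "Branded Drug" = 6.5,
    "Clinical Drug Box" = 7, "Branded Drug Box" = 7.5,
    "Quantified Clinical Drug" = 8, "Quantified Branded Drug" = 8.5,
    "Quantified Clinical Drug Box" = 9, "Quantified Branded Drug Box" = 9.5,
    "Clinical Pack" = 10, "Branded Pack" = 10.5,
    "Clinical Pack Box" = 11, "Branded Pack Box" = 11.5,
    "Marketed Product" = 12)
}

#' Granularity rank of one or more concept classes
#'
#' @param concept_class character vector of concept class labels
#' @return numeric vector; `NA` for classes outside the drug hierarchy
#'   (ATC, CTD and other non-drug classes)
#' @export
granularity_rank <- function(concept_class) {
  unname(granularity_order()[concept_class])
}

# Unit conversion table: per source spelling, the canonical unit and the
# multiplicative factor into it. Mass canonicalises to milligrams, volume to
# millilitres; dimensionless dose units (units, actuations) pass through.
default_unit_table <- function() {
  list(
    "mg"  = list(unit = "mg", factor = 1),
    "g"   = list(unit = "mg", factor = 1000),
    "kg"  = list(unit = "mg", factor = 1e6),
    "mcg" = list(unit = "mg", factor = 1e-3),
    "ug"  = list(unit = "mg", factor = 1e-3),
    "µg" = list(unit = "mg", factor = 1e-3),
    "ng"  = list(unit = "mg", factor = 1e-9),
    "ml"  = list(unit = "mL", factor = 1),
    "l"   = list(unit = "mL", factor = 1000),
    "dl"  = list(unit = "mL", factor = 100),
    "ul"  = list(unit = "mL", factor = 1e-3),
    "µl" = list(unit = "mL", factor = 1e-3),
    "unt" = list(unit = "UNT", factor = 1),
    "iu"  = list(unit = "UNT", factor = 1),
    "i.e." = list(unit = "UNT", factor = 1),
    "ie"  = list(unit = "UNT", factor = 1),
    "act" = list(unit = "ACT", factor = 1),
    "actuat" = list(unit = "ACT", factor = 1)
  )
}

#' Pipeline tuning parameters
#'
#' @param alpha dose-form vote acceptance threshold: a dose form is accepted
#'   when its accumulated vote weight reaches `alpha` times the maximum
#'   weight in its tally. In (0, 1]; 1 keeps only the top-voted form(s).
#' @param strength_tol relative tolerance when comparing normalized strength
#'   and quantity values
#' @param brand_min_token_chars minimum character length of a brand name
#'   consisting of a single token for it to be eligible as a prefix match
#'   (suppresses spurious one-token hits)
#' @param second_pass_votes recollect dose-form votes (from scratch, to avoid
#'   double counting) once clinical drug component candidates exist
#' @param source_vocabulary_id label written into the Usagi output
#' @param source_system URI of the source code system in FHIR ConceptMaps
#' @param target_systems named character vector mapping target vocabulary ids
#'   to code system URIs
#' @param unit_table unit conversion table; see `default_unit_table`
#' @param created_by provenance string for generated mapping rows
#' @return a named list of class `rx_pipeline_config`
#' @export
pipeline_config <- function(alpha = 0.5,
                            strength_tol = 1e-4,
                            brand_min_token_chars = 3,
                            second_pass_votes = TRUE,
                            source_vocabulary_id = "SOURCE",
                            source_system = "urn:example:source-drug-codes",
                            target_systems = c(
                              "RxNorm" = "http://www.nlm.nih.gov/research/umls/rxnorm",
                              "RxNorm Extension" = "urn:omop:rxnorm-extension"),
                            unit_table = default_unit_table(),
                            created_by = "rxnemap") {
  stopifnot(alpha > 0, alpha <= 1, strength_tol >= 0)
  structure(list(
    alpha = alpha,
    strength_tol = strength_tol,
    brand_min_token_chars = brand_min_token_chars,
    second_pass_votes = second_pass_votes,
    source_vocabulary_id = source_vocabulary_id,
    source_system = source_system,
    target_systems = target_systems,
    unit_table = unit_table,
    created_by = created_by
  ), class = "rx_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [pipeline_config()] and
#' [graph_config()]; unknown keys are ignored with a warning. Used by the
#' command-line interface.
#'
#' @param path YAML file
#' @return list with elements `pipeline` and `graph`
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pc_args <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  gc_args <- raw[intersect(names(raw), names(formals(graph_config)))]
  extra <- setdiff(names(raw), c(names(formals(pipeline_config)),
                                 names(formals(graph_config)),
                                 c("paths")))
  if (length(extra)) rx_log("warn", "ignoring unknown config keys: ",
                            paste(extra, collapse = ", "))
  list(pipeline = do.call(pipeline_config, pc_args),
       graph = do.call(graph_config, gc_args),
       paths = raw$paths)
}
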