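# Strength/quantity normalization and hierarchical refinement: from
# ingredient candidates up through clinical drug components, (branded)
# clinical drugs, quantified forms and boxes to the finest attainable
# concept class.

#' Normalize a quantity to canonical units
#'
#' Converts to the canonical unit of its dimension (mass: milligram, volume:
#' millilitre; dose units and actuations pass through). Compound
#' concentration units ("mg/ml") are normalized on both sides of the slash.
#' A percent strength is converted only when the weight-per-volume
#' convention is explicit ("% w/v", to 10 mg/mL per percent point);
#' a bare "%" is not interpretable and raises a unit error, as does any
#' unit absent from the conversion table.
#'
#' @param value positive numeric
#' @param unit unit string as distributed
#' @param unit_table conversion table, see [pipeline_config()]
#' @return list with `value` and canonical `unit`
#' @export
normalize_quantity <- function(value, unit, unit_table = default_unit_table()) {
  value <- as.numeric(value)
  if (is.na(value) || is.na(unit)) unit_error("missing value or unit")
  u <- tolower(trimws(unit))
  if (u %in% c("% w/v", "%w/v")) {
    return(list(value = value * 10, unit = "mg/mL"))
  }
  if (grepl("/", u, fixed = TRUE)) {
    parts <- strsplit(u, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2) unit_error(paste0("cannot parse unit: ", unit))
    num <- normalize_quantity(value, parts[1], unit_table)
    den <- lookup_unit(parts[2], unit_table)
    return(list(value = num$value / den$factor,
                unit = paste0(num$unit, "/", den$unit)))
  }
  cu <- lookup_unit(u, unit_table)
  list(value = value * cu$factor, unit = cu$unit)
}

lookup_unit <- function(u, unit_table) {
  entry <- unit_table[[tolower(trimws(u))]]
  if (is.null(entry)) unit_error(paste0("unknown unit: ", u))
  entry
}

# symmetric relative comparison of two normalized quantities
quantity_matches <- function(a, b, tol = 1e-4) {
  if (!identical(a$unit, b$unit)) return(FALSE)
  if (a$value == b$value) return(TRUE)
  abs(a$value - b$value) <= tol * max(abs(a$value), abs(b$value))
}

# normalized strength of one strength-table row with respect to one
# ingredient; NULL when the row carries no usable strength
row_strength <- function(row, unit_table) {
  if (!is.na(row$amount_value) && nzchar(row$amount_unit %||% "")) {
    return(tryCatch(normalize_quantity(row$amount_value, row$amount_unit,
                                       unit_table),
                    rxnemap_unit_error = function(e) NULL))
  }
  if (!is.na(row$numerator_value) && nzchar(row$numerator_unit %||% "")) {
    den_val <- if (is.na(row$denominator_value)) 1 else as.numeric(row$denominator_value)
    den_unit <- row$denominator_unit %||% NA_character_
    if (is.na(den_unit) || !nzchar(den_unit)) return(NULL)
    return(tryCatch({
      num <- normalize_quantity(as.numeric(row$numerator_value),
                                row$numerator_unit, unit_table)
      den <- normalize_quantity(den_val, den_unit, unit_table)
      list(value = num$value / den$value,
           unit = paste0(num$unit, "/", den$unit))
    }, rxnemap_unit_error = function(e) NULL))
  }
  NULL
}

# source strength normalized; NULL when absent or not convertible
source_strength <- function(ing, unit_table) {
  if (is.na(ing$strength_value) || is.na(ing$strength_unit) ||
      !nzchar(ing$strength_unit)) return(NULL)
  tryCatch(normalize_quantity(ing$strength_value, ing$strength_unit, unit_table),
           rxnemap_unit_error = function(e) {
             rx_log("warn", "ingredient '", ing$raw_name, "': ",
                    conditionMessage(e), "; strength ignored")
             NULL
           })
}

#' Derive clinical drug component candidates from mapped ingredients
#'
#' For every source ingredient with a usable normalized strength, finds the
#' component concepts of its candidate target ingredients whose strength row
#' matches within the relative tolerance. Ingredients without usable
#' strength yield an empty component set (mapping then stops at ingredient
#' level for that drug). Multiple matching components are all retained.
#'
#' @param drug a [source_drug()]
#' @param ingredient_candidates candidate data.frame (see [map_ingredients()])
#' @param graph a `concept_graph` with strength rows loaded
#' @param config a [pipeline_config()]
#' @return named list: per source ingredient raw name, an integer vector of
#'   Clinical Drug Comp concept ids
#' @export
derive_cdc <- function(drug, ingredient_candidates, graph,
                       config = pipeline_config()) {
  out <- list()
  for (ing in active_ingredients(drug)) {
    out[[ing$raw_name]] <- integer()
    src <- source_strength(ing, config$unit_table)
    if (is.null(src)) next
    targets <- unique(ingredient_candidates$target_concept_id[
      ingredient_candidates$source_ingredient == ing$raw_name])
    comps <- integer()
    for (t in targets) {
      cand <- related_in_ids(graph, t, graph$config$rel_has_ingredient)
      cand <- cand[concept_class_of(graph, cand) == "Clinical Drug Comp"]
      for (cc in cand) {
        rows <- strength_rows_of(graph, cc)
        rows <- rows[rows$ingredient_concept_id == t, , drop = FALSE]
        for (k in seq_len(nrow(rows))) {
          rs <- row_strength(rows[k, ], config$unit_table)
          if (!is.null(rs) && quantity_matches(src, rs, config$strength_tol)) {
            comps <- c(comps, cc)
            break
          }
        }
      }
    }
    out[[ing$raw_name]] <- sort(unique(comps))
  }
  out
}

#' Refine clinical candidates with brand evidence
#'
#' Derives the branded counterparts of a set of clinical candidates (the
#' concepts that are tradenames of a candidate and carry the matched brand
#' name) and, when at least one branded counterpart exists, narrows the
#' clinical set to those candidates that underlie a branded one. Without a
#' brand, or when no branded concept exists, the clinical set is returned
#' unchanged and the branded set is empty: no evidence, no narrowing.
#'
#' @param clinical_ids integer vector of clinical candidate concept ids
#' @param brand_concept_id matched brand concept id or `NULL`
#' @param graph a `concept_graph`
#' @return list with `clinical` and `branded` integer vectors
#' @export
refine_branded <- function(clinical_ids, brand_concept_id, graph) {
  clinical_ids <- sort(unique(as.integer(clinical_ids)))
  if (is.null(brand_concept_id) || is.na(brand_concept_id) ||
      !length(clinical_ids)) {
    return(list(clinical = clinical_ids, branded = integer()))
  }
  cfg <- graph$config
  branded <- integer()
  for (cl in clinical_ids) {
    b <- related_in_ids(graph, cl, cfg$rel_tradename_of)
    if (!length(b)) next
    has_brand <- vapply(b, function(x)
      brand_concept_id %in% related_ids(graph, x, cfg$rel_has_brand_name),
      logical(1))
    branded <- c(branded, b[has_brand])
  }
  branded <- sort(unique(branded))
  if (!length(branded)) {
    return(list(clinical = clinical_ids, branded = integer()))
  }
  underlying <- sort(unique(unlist(lapply(branded, function(b)
    related_ids(graph, b, cfg$rel_tradename_of)), use.names = FALSE)))
  list(clinical = intersect(clinical_ids, underlying), branded = branded)
}

#' Derive clinical drug candidates
#'
#' Combines the per-ingredient component candidates with the mapped dose
#' forms: a clinical drug qualifies when its component set consists of
#' exactly one candidate component per source ingredient (component count
#' equal to the ingredient count; partial covers are rejected) and its dose
#' form is among the mapped forms.
#'
#' @param drug a [source_drug()]
#' @param cdc_sets named list from [derive_cdc()]
#' @param doseform_ids integer vector of mapped dose-form concept ids
#' @param graph a `concept_graph`
#' @return integer vector of Clinical Drug concept ids
#' @export
derive_cd <- function(drug, cdc_sets, doseform_ids, graph) {
  n_ing <- length(active_ingredients(drug))
  if (n_ing == 0 || length(cdc_sets) < n_ing || !length(doseform_ids))
    return(integer())
  if (any(vapply(cdc_sets, length, 0L) == 0)) return(integer())
  cfg <- graph$config
  all_cdcs <- unlist(cdc_sets, use.names = FALSE)
  cds <- sort(unique(unlist(lapply(cdc_sets[[1]], function(cc)
    related_in_ids(graph, cc, cfg$rel_consists_of)), use.names = FALSE)))
  cds <- cds[concept_class_of(graph, cds) == "Clinical Drug"]
  keep <- vapply(cds, function(cd) {
    comps <- related_ids(graph, cd, cfg$rel_consists_of)
    if (length(comps) != n_ing) return(FALSE)
    if (!all(comps %in% all_cdcs)) return(FALSE)
    per_ing <- vapply(cdc_sets, function(s) any(comps %in% s), logical(1))
    if (!all(per_ing)) return(FALSE)
    forms <- related_ids(graph, cd, cfg$rel_has_dose_form)
    any(forms %in% doseform_ids)
  }, logical(1))
  cds[keep]
}

# quantity factor of a quantified concept, from the denominator of its
# strength rows (the total size of the formulation); NULL when absent
quantity_factor <- function(graph, concept_id, unit_table) {
  rows <- strength_rows_of(graph, concept_id)
  rows <- rows[!is.na(rows$denominator_value) &
                 nzchar(rows$denominator_unit %||% ""), , drop = FALSE]
  if (!nrow(rows)) return(NULL)
  tryCatch(normalize_quantity(as.numeric(rows$denominator_value[1]),
                              rows$denominator_unit[1], unit_table),
           rxnemap_unit_error = function(e) NULL)
}

#' Derive quantified drug candidates from total size
#'
#' Liquid and gas formulations carry a total size (volume or actuations);
#' the quantified concepts related to a candidate (branded) clinical drug
#' whose quantity factor equals the normalized total size within tolerance
#' are selected. Without size information the result is empty.
#'
#' @param cd_candidates integer vector of (branded) clinical drug ids
#' @param total_size normalized quantity (list with `value`, `unit`) or
#'   `NULL`
#' @param graph a `concept_graph`
#' @param config a [pipeline_config()]
#' @return integer vector of quantified concept ids
#' @export
derive_quantified <- function(cd_candidates, total_size, graph,
                              config = pipeline_config()) {
  if (is.null(total_size) || !length(cd_candidates)) return(integer())
  cfg <- graph$config
  out <- integer()
  for (cd in cd_candidates) {
    q <- related_in_ids(graph, cd, cfg$rel_quantified_form_of)
    for (qc in q) {
      f <- quantity_factor(graph, qc, config$unit_table)
      if (!is.null(f) && quantity_matches(total_size, f, config$strength_tol)) {
        out <- c(out, qc)
      }
    }
  }
  sort(unique(out))
}

#' Derive box-class candidates from the box size
#'
#' Box concepts related to a candidate whose box-size attribute equals the
#' source box size exactly (integer comparison). Without a box size the
#' result is empty.
#'
#' @param candidates integer vector of candidate ids (clinical/branded,
#'   plain or quantified)
#' @param box_size integer box size or `NA`
#' @param graph a `concept_graph`
#' @return integer vector of box concept ids
#' @export
derive_boxes <- function(candidates, box_size, graph) {
  if (is.null(box_size) || is.na(box_size) || !length(candidates))
    return(integer())
  cfg <- graph$config
  out <- integer()
  for (cd in candidates) {
    boxes <- related_in_ids(graph, cd, cfg$rel_box_of)
    for (b in boxes) {
      rows <- strength_rows_of(graph, b)
      bs <- rows$box_size[!is.na(rows$box_size)]
      if (length(bs) && as.integer(bs[1]) == as.integer(box_size)) {
        out <- c(out, b)
      }
    }
  }
  sort(unique(out))
}
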