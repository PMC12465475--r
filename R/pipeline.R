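# Pipe-and-filter orchestration: ingredients -> dose forms -> brands ->
# hierarchical refinement -> finalized mapping rows plus summary statistics.

# concept classes that are admissible final mapping targets (components and
# drug forms are used implicitly during refinement but are not targets)
TARGET_CLASSES <- c("Ingredient", "Precise Ingredient",
                    "Clinical Drug", "Branded Drug",
                    "Clinical Drug Box", "Branded Drug Box",
                    "Quantified Clinical Drug", "Quantified Branded Drug",
                    "Quantified Clinical Drug Box", "Quantified Branded Drug Box",
                    "Clinical Pack", "Branded Pack",
                    "Clinical Pack Box", "Branded Pack Box")

# anchor concepts for the dose-form vote of one drug: mapped ingredient
# candidates, lateral targets of its ATC codes, and its matched brand
vote_anchors <- function(drug, ing_cands, brand_id, graph) {
  atc_targets <- unlist(lapply(drug$atc_codes, function(code) {
    atc_ids <- concepts_by_code(graph, code, vocabulary_id = "ATC")
    unlist(lapply(atc_ids, function(a)
      related_ids(graph, a, graph$config$rel_atc_ingredient)),
      use.names = FALSE)
  }), use.names = FALSE)
  unique(c(ing_cands$target_concept_id, atc_targets,
           if (!is.null(brand_id)) brand_id))
}

#' Run the full mapping pipeline on in-memory inputs
#'
#' Executes the stages in order -- brand prefix matching, the five
#' ingredient strategies with ATC precedence, dose-form mapping
#' (registration path with probabilistic voting as fallback), component
#' derivation from strengths, brand refinement, a second vote pass anchored
#' on drug components (tallies recomputed from scratch to avoid double
#' counting), clinical/branded drug derivation, quantified and box
#' refinement -- then finalizes one mapping row per (source code, target),
#' applies manual overrides and preserves previously approved rows.
#'
#' @param graph a `concept_graph`
#' @param drugs list of [source_drug()]s
#' @param links a `crosslinks`
#' @param overrides optional manual-override data.frame (see
#'   [read_overrides()])
#' @param previous optional previously reviewed mapping rows (see
#'   [read_usagi()])
#' @param config a [pipeline_config()]
#' @return list of class `rx_mapping` with elements `rows` (mapping rows),
#'   `summary` (per-class counts and single/multi target shares),
#'   `candidate_sets`, `doseforms`, `brands`, `ingredients` and `tallies`
#' @export
run_pipeline <- function(graph, drugs, links, overrides = NULL,
                         previous = NULL, config = pipeline_config()) {
  if (!length(drugs)) {
    rows <- empty_mapping_rows()
    if (!is.null(previous)) rows <- merge_previous(rows, previous)
    return(structure(list(rows = rows, summary = mapping_summary(rows),
                          candidate_sets = list(), doseforms = list(),
                          brands = list(), ingredients = list(),
                          tallies = list()),
                     class = "rx_mapping"))
  }
  pzns <- vapply(drugs, `[[`, "", "pzn")

  rx_log("info", "stage 1/5: brand matching over ", length(drugs), " drugs")
  brands <- lapply(drugs, function(d)
    match_brand(d$name, graph, config$brand_min_token_chars))
  names(brands) <- pzns
  rx_log("info", "  brands matched: ",
         sum(!vapply(brands, is.null, logical(1))))

  rx_log("info", "stage 2/5: ingredient mapping")
  ingredients <- lapply(seq_along(drugs), function(i)
    map_ingredients(drugs[[i]], links, graph,
                    brands[[i]]$brand_concept_id))
  names(ingredients) <- pzns
  rx_log("info", "  drugs with ingredient candidates: ",
         sum(vapply(ingredients, nrow, 0L) > 0))

  rx_log("info", "stage 3/5: dose-form mapping (vote pass 1)")
  anchors <- lapply(seq_along(drugs), function(i)
    vote_anchors(drugs[[i]], ingredients[[i]],
                 brands[[i]]$brand_concept_id, graph))
  names(anchors) <- pzns
  tallies <- collect_votes(drugs, anchors, graph)
  doseforms <- decide_drug_doseforms(drugs, links, tallies, config$alpha)

  rx_log("info", "stage 4/5: component derivation and refinement")
  cdc_sets <- vector("list", length(drugs))
  bdc_sets <- vector("list", length(drugs))
  for (i in seq_along(drugs)) {
    sets <- derive_cdc(drugs[[i]], ingredients[[i]], graph, config)
    brand_id <- brands[[i]]$brand_concept_id
    bdc <- integer()
    if (!is.null(brand_id)) {
      sets <- lapply(sets, function(ids) {
        ref <- refine_branded(ids, brand_id, graph)
        bdc <<- c(bdc, ref$branded)
        ref$clinical
      })
    }
    cdc_sets[[i]] <- sets
    bdc_sets[[i]] <- sort(unique(bdc))
  }

  if (isTRUE(config$second_pass_votes)) {
    rx_log("info", "  vote pass 2 (component-anchored, recomputed from scratch)")
    anchors2 <- lapply(seq_along(drugs), function(i)
      unique(c(anchors[[i]], unlist(cdc_sets[[i]], use.names = FALSE),
               bdc_sets[[i]])))
    names(anchors2) <- pzns
    tallies <- collect_votes(drugs, anchors2, graph)
    doseforms <- decide_drug_doseforms(drugs, links, tallies, config$alpha)
  }

  rx_log("info", "stage 5/5: drug-level derivation and finalization")
  candidate_sets <- vector("list", length(drugs))
  for (i in seq_along(drugs)) {
    drug <- drugs[[i]]
    brand_id <- brands[[i]]$brand_concept_id
    forms <- doseforms[[drug$pzn]] %||% integer()
    cd <- derive_cd(drug, cdc_sets[[i]], forms, graph)
    ref <- refine_branded(cd, brand_id, graph)
    cd <- ref$clinical; bd <- ref$branded
    total <- NULL
    if (!is.na(drug$total_value) && !is.na(drug$total_unit) &&
        nzchar(drug$total_unit)) {
      total <- tryCatch(
        normalize_quantity(drug$total_value, drug$total_unit, config$unit_table),
        rxnemap_unit_error = function(e) {
          rx_log("warn", "drug ", drug$pzn, ": ", conditionMessage(e),
                 "; size ignored")
          NULL
        })
    }
    qcd <- derive_quantified(cd, total, graph, config)
    qbd <- derive_quantified(bd, total, graph, config)
    boxes <- derive_boxes(c(cd, bd, qcd, qbd), drug$box_size, graph)
    evidence <- list(
      ingredient = nrow(ingredients[[i]]) > 0,
      dose_form = length(forms) > 0,
      strength = any(vapply(cdc_sets[[i]], length, 0L) > 0),
      brand = !is.null(brand_id),
      quantity_or_box = length(c(qcd, qbd, boxes)) > 0)
    ids <- c(unique(ingredients[[i]]$target_concept_id),
             unlist(cdc_sets[[i]], use.names = FALSE), bdc_sets[[i]],
             cd, bd, qcd, qbd, boxes)
    candidate_sets[[i]] <- candidate_set(drug$pzn, ids, graph, evidence)
  }
  names(candidate_sets) <- pzns

  rows <- do.call(rbind, lapply(seq_along(drugs), function(i)
    finalize(candidate_sets[[i]], graph, overrides, config,
             source_name = drugs[[i]]$name)))
  # overrides for source codes outside the dataset are kept as provided
  if (!is.null(overrides) && nrow(overrides)) {
    extra <- overrides[!overrides$source_code %in% pzns, , drop = FALSE]
    if (nrow(extra)) {
      rx_log("warn", nrow(extra), " override(s) for source code(s) not in ",
             "the dataset; kept as provided")
      rows <- rbind(rows, do.call(rbind, lapply(seq_len(nrow(extra)),
        function(i) {
          tid <- as.integer(extra$target_concept_id[i])
          known <- has_concept(graph, tid)
          mapping_row(extra$source_code[i], "", tid,
                      target_vocabulary_id = if (known)
                        concept(graph, tid)$vocabulary_id else "",
                      target_class = if (known)
                        concept_class_of(graph, tid) else "",
                      match_score = 1, status = "APPROVED",
                      equivalence_hint = "EQUAL",
                      comment = paste0("manual override: ",
                                       extra$comment[i] %||% ""),
                      created_by = config$created_by,
                      status_set_by = config$created_by)
        })))
    }
  }
  if (!is.null(previous)) rows <- merge_previous(rows, previous)
  rows <- sort_mapping_rows(rows)
  rownames(rows) <- NULL
  res <- structure(list(rows = rows, summary = mapping_summary(rows),
                        candidate_sets = candidate_sets,
                        doseforms = doseforms, brands = brands,
                        ingredients = ingredients, tallies = tallies),
                   class = "rx_mapping")
  rx_log("info", "pipeline complete: ", nrow(rows), " mapping rows for ",
         length(drugs), " drugs")
  res
}

#' Summarize mapping rows
#'
#' Counts source codes per final target concept class (a multi-target drug
#' is counted once per class it maps into), the unmapped share, and the
#' single/multi-target shares.
#'
#' @param rows mapping-row data.frame
#' @return list with `by_class` (data.frame class/count), `n_source`,
#'   `n_unmapped`, `share_single_target`, `share_2_to_5`, `share_over_5`
#' @export
mapping_summary <- function(rows) {
  codes <- unique(rows$source_code)
  mapped <- rows[rows$target_concept_id > 0, , drop = FALSE]
  per_code <- table(mapped$source_code)
  n_targets <- as.integer(per_code[match(codes, names(per_code))])
  n_targets[is.na(n_targets)] <- 0L
  cls <- unique(mapped[c("source_code", "target_class")])
  by_class <- as.data.frame(table(class = cls$target_class),
                            stringsAsFactors = FALSE)
  names(by_class) <- c("concept_class", "n_source_codes")
  by_class <- by_class[order(-granularity_rank(by_class$concept_class)), ,
                       drop = FALSE]
  rownames(by_class) <- NULL
  n_mapped_codes <- sum(n_targets > 0)
  list(
    by_class = by_class,
    n_source = length(codes),
    n_unmapped = sum(n_targets == 0),
    share_single_target = if (n_mapped_codes) mean(n_targets[n_targets > 0] == 1) else NA_real_,
    share_2_to_5 = if (n_mapped_codes) mean(n_targets[n_targets > 0] >= 2 &
                                            n_targets[n_targets > 0] <= 5) else NA_real_,
    share_over_5 = if (n_mapped_codes) mean(n_targets[n_targets > 0] > 5) else NA_real_)
}

#' @export
print.rx_mapping <- function(x, ...) {
  s <- x$summary
  cat("<rx_mapping> ", s$n_source, " source codes, ",
      s$n_source - s$n_unmapped, " mapped (",
      if (s$n_source) round(100 * (1 - s$n_unmapped / s$n_source), 2) else 0,
      "%)\n", sep = "")
  if (nrow(s$by_class)) {
    for (i in seq_len(nrow(s$by_class))) {
      cat(sprintf("  %-30s %d\n", s$by_class$concept_class[i],
                  s$by_class$n_source_codes[i]))
    }
  }
  if (!is.na(s$share_single_target)) {
    cat("  single-target share: ", round(100 * s$share_single_target, 2),
        "%\n", sep = "")
  }
  invisible(x)
}

#' Run the pipeline from files, writing its artifacts
#'
#' File-level driver used by the command-line interface: loads the
#' vocabulary store, source terminology, supplement and cross-link tables,
#' runs [run_pipeline()] and writes the Usagi CSV, the summary table and the
#' dose-form vote diagnostics.
#'
#' @param paths named list with elements `concept`, `relationship`,
#'   `strength`, `source`, `supplement`, `translations`, `cas`,
#'   `alignment`, `registration`, optionally `overrides`, `previous`,
#'   and output paths `usagi_out`, `summary_out`, `tallies_out`
#' @param config a [pipeline_config()]
#' @param graph_cfg a [graph_config()]
#' @return the `rx_mapping` result, invisibly
#' @export
run_pipeline_files <- function(paths, config = pipeline_config(),
                               graph_cfg = graph_config()) {
  graph <- load_athena_tables(paths$concept, paths$relationship,
                              paths$strength, graph_cfg)
  drugs <- load_source(paths$source, paths$supplement)
  links <- load_crosslinks(paths$translations, paths$cas, paths$alignment,
                           paths$registration, graph = graph)
  overrides <- if (!is.null(paths$overrides))
    read_overrides(paths$overrides, vapply(drugs, `[[`, "", "pzn")) else NULL
  previous <- if (!is.null(paths$previous)) read_usagi(paths$previous) else NULL
  res <- run_pipeline(graph, drugs, links, overrides, previous, config)
  if (!is.null(paths$usagi_out)) {
    write_usagi(res$rows, paths$usagi_out, config$source_vocabulary_id)
  }
  if (!is.null(paths$summary_out)) {
    utils::write.csv(res$summary$by_class, paths$summary_out,
                     row.names = FALSE)
  }
  if (!is.null(paths$tallies_out)) {
    utils::write.csv(tallies_as_table(res$tallies), paths$tallies_out,
                     row.names = FALSE)
  }
  invisible(res)
}
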