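# Candidate-set bookkeeping and finalization into mapping rows.

#' Assemble a per-drug candidate set across concept classes
#'
#' Classifies candidate concept ids by concept class and records which kinds
#' of evidence (ingredient, dose form, strength, brand, quantity/box)
#' contributed. The final class is the populated class of maximal
#' granularity rank.
#'
#' @param pzn source code
#' @param candidate_ids integer vector of all candidate concept ids gathered
#'   during refinement
#' @param graph a `concept_graph`
#' @param evidence named logical list with elements `ingredient`,
#'   `dose_form`, `strength`, `brand`, `quantity_or_box`
#' @return object of class `candidate_set` with fields `drug`, `per_class`,
#'   `final_class` (or `"UNMAPPED"`), `final_targets`, `evidence`
#' @export
candidate_set <- function(pzn, candidate_ids, graph, evidence = list()) {
  candidate_ids <- sort(unique(as.integer(candidate_ids)))
  cls <- concept_class_of(graph, candidate_ids)
  per_class <- split(candidate_ids, cls)
  # components and drug forms are refinement intermediates, not targets
  eligible <- intersect(names(per_class), TARGET_CLASSES)
  ranks <- granularity_rank(eligible)
  if (length(eligible) && any(!is.na(ranks))) {
    final_class <- eligible[which.max(ranks)]
    final_targets <- per_class[[final_class]]
  } else {
    final_class <- "UNMAPPED"
    final_targets <- integer()
  }
  structure(list(drug = pzn, per_class = per_class,
                 final_class = final_class, final_targets = final_targets,
                 evidence = evidence),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> ", x$drug, " -> ", x$final_class,
      if (length(x$final_targets))
        paste0(" {", paste(x$final_targets, collapse = ", "), "}") else "",
      "\n", sep = "")
  invisible(x)
}

empty_mapping_rows <- function() {
  data.frame(source_code = character(), source_name = character(),
             target_concept_id = integer(), target_vocabulary_id = character(),
             target_class = character(),
             match_score = numeric(), status = character(),
             equivalence_hint = character(), comment = character(),
             created_by = character(), status_set_by = character(),
             stringsAsFactors = FALSE)
}

mapping_row <- function(source_code, source_name, target_concept_id = 0L,
                        target_vocabulary_id = "", target_class = "",
                        match_score = 0, status = "UNCHECKED",
                        equivalence_hint = "UNMATCHED", comment = "",
                        created_by = "rxnemap", status_set_by = "") {
  data.frame(source_code = source_code, source_name = source_name,
             target_concept_id = as.integer(target_concept_id),
             target_vocabulary_id = target_vocabulary_id,
             target_class = target_class,
             match_score = match_score, status = status,
             equivalence_hint = equivalence_hint, comment = comment,
             created_by = created_by, status_set_by = status_set_by,
             stringsAsFactors = FALSE)
}

match_score_of <- function(evidence) {
  s <- 0
  if (isTRUE(evidence$ingredient)) s <- s + 0.3
  if (isTRUE(evidence$dose_form)) s <- s + 0.2
  if (isTRUE(evidence$strength)) s <- s + 0.2
  if (isTRUE(evidence$quantity_or_box)) s <- s + 0.15
  if (isTRUE(evidence$brand)) s <- s + 0.15
  min(s, 1)
}

equivalence_hint_of <- function(final_class) {
  rank <- granularity_rank(final_class)
  if (is.na(rank)) return("RELATED")
  if (final_class %in% INGREDIENT_CLASSES) return("WIDER")
  box_classes <- c("Clinical Drug Box", "Branded Drug Box",
                   "Quantified Clinical Drug Box", "Quantified Branded Drug Box",
                   "Clinical Pack Box", "Branded Pack Box")
  if (final_class %in% box_classes) return("EQUAL")
  "RELATED"
}

#' Finalize a candidate set into mapping rows
#'
#' Manual override rows for the source code win unconditionally (they are
#' the channel for pack mappings, which are not derivable automatically).
#' Otherwise the final class is the populated class of maximal granularity
#' rank, falling back down to the ingredient baseline, and one row per final
#' target is emitted. A drug with nothing populated is emitted as a single
#' unmapped row (target 0). The match score is an explicit evidence
#' heuristic: 0.3 for a mapped ingredient, plus 0.2 each for dose form and
#' strength and 0.15 each for brand and quantity/box evidence, capped at 1.
#'
#' @param candset a [candidate_set()]
#' @param graph a `concept_graph`
#' @param manual_overrides data.frame with columns `source_code`,
#'   `target_concept_id`, `comment` (or `NULL`)
#' @param config a [pipeline_config()]
#' @param source_name product name for the output rows
#' @return data.frame of mapping rows
#' @export
finalize <- function(candset, graph, manual_overrides = NULL,
                     config = pipeline_config(), source_name = "") {
  pzn <- candset$drug
  if (!is.null(manual_overrides) && nrow(manual_overrides)) {
    ov <- manual_overrides[manual_overrides$source_code == pzn, , drop = FALSE]
    if (nrow(ov)) {
      rows <- lapply(seq_len(nrow(ov)), function(i) {
        tid <- as.integer(ov$target_concept_id[i])
        known <- has_concept(graph, tid)
        mapping_row(pzn, source_name, tid,
                    target_vocabulary_id = if (known)
                      concept(graph, tid)$vocabulary_id else "",
                    target_class = if (known) concept_class_of(graph, tid) else "",
                    match_score = 1, status = "APPROVED",
                    equivalence_hint = "EQUAL",
                    comment = paste0("manual override",
                                     if (nzchar(ov$comment[i] %||% ""))
                                       paste0(": ", ov$comment[i]) else ""),
                    created_by = config$created_by,
                    status_set_by = config$created_by)
      })
      return(do.call(rbind, rows))
    }
  }
  if (candset$final_class == "UNMAPPED" || !length(candset$final_targets)) {
    return(mapping_row(pzn, source_name, 0L, comment = "no candidate found",
                       created_by = config$created_by))
  }
  provenance <- paste0(
    "final class: ", candset$final_class, "; evidence: ",
    paste(names(Filter(isTRUE, candset$evidence)), collapse = "+"))
  rows <- lapply(candset$final_targets, function(tid) {
    mapping_row(pzn, source_name, tid,
                target_vocabulary_id = concept(graph, tid)$vocabulary_id,
                target_class = candset$final_class,
                match_score = match_score_of(candset$evidence),
                equivalence_hint = equivalence_hint_of(candset$final_class),
                comment = provenance, created_by = config$created_by)
  })
  do.call(rbind, rows)
}

#' Read a manual override table
#'
#' @param path CSV with columns `source_code`, `target_concept_id`,
#'   `comment`
#' @param known_codes optional character vector; overrides referencing a
#'   source code outside it are kept but logged
#' @return data.frame
#' @export
read_overrides <- function(path, known_codes = NULL) {
  ov <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", colClasses = "character")
  miss <- setdiff(c("source_code", "target_concept_id"), names(ov))
  if (length(miss)) format_error(paste0("override table lacks column(s): ",
                                        paste(miss, collapse = ", ")))
  if (is.null(ov$comment)) ov$comment <- ""
  if (!is.null(known_codes)) {
    unknown <- setdiff(ov$source_code, known_codes)
    if (length(unknown)) {
      rx_log("warn", "override(s) for unknown source code(s): ",
             paste(unknown, collapse = ", "), "; kept as provided")
    }
  }
  ov
}
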