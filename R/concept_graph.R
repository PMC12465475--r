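# Indexed store over OMOP-style vocabulary tables: concepts, typed directed
# relationships and drug strength rows, with hierarchy traversal (ancestor
# closure, finest common ancestors) over the configured upward links.

#' Construct a concept graph from in-memory tables
#'
#' @param concepts data.frame with columns `concept_id`, `concept_name`,
#'   `vocabulary_id`, `concept_class_id`, `standard_concept` (logical or
#'   "S"/"" flag), `concept_code`
#' @param relationships data.frame with columns `concept_id_1`,
#'   `concept_id_2`, `relationship_id`
#' @param strengths optional data.frame with columns `drug_concept_id`,
#'   `ingredient_concept_id`, `amount_value`, `amount_unit`,
#'   `numerator_value`, `numerator_unit`, `denominator_value`,
#'   `denominator_unit`, `box_size`
#' @param config a [graph_config()]
#' @return an object of class `concept_graph`
#' @details Relationship rows whose endpoints are not in `concepts` raise an
#'   integrity error; duplicate `(source, target, relationship_id)` triples
#'   are dropped with a warning. Cycles among the hierarchy edges are
#'   tolerated by the traversal (visited-set closure) but reported with a
#'   warning listing the concepts involved.
#' @export
concept_graph <- function(concepts, relationships,
                          strengths = NULL, config = graph_config()) {
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  relationships <- as.data.frame(relationships, stringsAsFactors = FALSE)
  need_c <- c("concept_id", "concept_name", "vocabulary_id",
              "concept_class_id", "standard_concept", "concept_code")
  miss <- setdiff(need_c, names(concepts))
  if (length(miss)) format_error(paste0("concept table lacks column(s): ",
                                        paste(miss, collapse = ", ")))
  need_r <- c("concept_id_1", "concept_id_2", "relationship_id")
  miss <- setdiff(need_r, names(relationships))
  if (length(miss)) format_error(paste0("relationship table lacks column(s): ",
                                        paste(miss, collapse = ", ")))
  concepts$concept_id <- as.integer(concepts$concept_id)
  if (anyDuplicated(concepts$concept_id)) {
    integrity_error(paste0("duplicate concept_id: ",
      paste(unique(concepts$concept_id[duplicated(concepts$concept_id)]),
            collapse = ", ")))
  }
  if (any(is.na(concepts$concept_name) | !nzchar(concepts$concept_name))) {
    integrity_error("concept_name must be non-empty for every concept")
  }
  if (!is.logical(concepts$standard_concept)) {
    concepts$standard_concept <- concepts$standard_concept %in% c("S", "C", "TRUE", "true")
  }
  relationships$concept_id_1 <- as.integer(relationships$concept_id_1)
  relationships$concept_id_2 <- as.integer(relationships$concept_id_2)
  dangling <- setdiff(c(relationships$concept_id_1, relationships$concept_id_2),
                      concepts$concept_id)
  if (length(dangling)) {
    integrity_error(paste0("relationship endpoint(s) missing from concept table: ",
                           paste(utils::head(dangling, 10), collapse = ", ")))
  }
  dup <- duplicated(relationships[need_r])
  if (any(dup)) {
    rx_log("warn", sum(dup), " duplicate relationship row(s) dropped")
    relationships <- relationships[!dup, , drop = FALSE]
  }
  if (!is.null(strengths)) {
    strengths <- as.data.frame(strengths, stringsAsFactors = FALSE)
    need_s <- c("drug_concept_id", "ingredient_concept_id")
    miss <- setdiff(need_s, names(strengths))
    if (length(miss)) format_error(paste0("strength table lacks column(s): ",
                                          paste(miss, collapse = ", ")))
    for (col in c("amount_value", "amount_unit", "numerator_value",
                  "numerator_unit", "denominator_value", "denominator_unit",
                  "box_size")) {
      if (is.null(strengths[[col]])) strengths[[col]] <- NA
    }
    strengths$drug_concept_id <- as.integer(strengths$drug_concept_id)
    strengths$ingredient_concept_id <- as.integer(strengths$ingredient_concept_id)
  } else {
    strengths <- data.frame(drug_concept_id = integer(), ingredient_concept_id = integer(),
                            amount_value = numeric(), amount_unit = character(),
                            numerator_value = numeric(), numerator_unit = character(),
                            denominator_value = numeric(), denominator_unit = character(),
                            box_size = integer(), stringsAsFactors = FALSE)
  }

  g <- new.env(parent = emptyenv())
  g$concepts <- concepts
  g$relationships <- relationships
  g$strengths <- strengths
  g$config <- config
  g$ids <- concepts$concept_id
  key1 <- as.character(relationships$concept_id_1)
  key2 <- as.character(relationships$concept_id_2)
  g$out_rows <- split(seq_len(nrow(relationships)), key1)
  g$in_rows <- split(seq_len(nrow(relationships)), key2)
  hier <- relationships$relationship_id %in% config$hierarchy_rels
  g$up <- split(relationships$concept_id_2[hier], key1[hier])
  g$down <- split(relationships$concept_id_1[hier], key2[hier])
  g$strength_rows <- split(seq_len(nrow(strengths)),
                           as.character(strengths$drug_concept_id))
  # lookup indexes
  g$code_key <- paste(concepts$vocabulary_id, concepts$concept_code, sep = "\r")
  ing <- concepts$concept_class_id %in% INGREDIENT_CLASSES
  nn <- norm_name(concepts$concept_name[ing])
  g$ing_name_index <- split(concepts$concept_id[ing], nn)
  # brand token index, grouped by first token
  br <- which(concepts$concept_class_id == "Brand Name")
  g$brand_tokens <- lapply(br, function(i) tokenize_name(concepts$concept_name[i]))
  g$brand_ids <- concepts$concept_id[br]
  first <- vapply(g$brand_tokens, function(t) if (length(t)) t[1] else "", "")
  keep <- nzchar(first)
  g$brand_by_first <- split(which(keep), first[keep])
  warn_hierarchy_cycles(g)
  class(g) <- "concept_graph"
  g
}

# Kahn-style elimination: nodes left after repeatedly removing sinks of the
# hierarchy subgraph are members of (or upstream of) a cycle.
warn_hierarchy_cycles <- function(g) {
  edges <- g$relationships[
    g$relationships$relationship_id %in% g$config$hierarchy_rels,
    c("concept_id_1", "concept_id_2"), drop = FALSE]
  if (!nrow(edges)) return(invisible())
  repeat {
    nodes <- unique(c(edges$concept_id_1, edges$concept_id_2))
    sinks <- setdiff(nodes, edges$concept_id_1)
    if (!length(sinks)) break
    edges <- edges[!(edges$concept_id_2 %in% sinks), , drop = FALSE]
    if (!nrow(edges)) return(invisible())
  }
  cyc <- unique(c(edges$concept_id_1, edges$concept_id_2))
  rx_log("warn", "hierarchy contains cycle(s) touching concept(s): ",
         paste(c_sort(cyc), collapse = ", "))
  invisible(cyc)
}

#' Load Athena-dialect vocabulary tables into a concept graph
#'
#' Reads `CONCEPT`, `CONCEPT_RELATIONSHIP` and (optionally) `DRUG_STRENGTH`
#' files in the dialect the OMOP vocabulary distribution uses: tab-separated,
#' header row, UTF-8, no quoting. Date and `invalid_reason` columns are
#' tolerated and ignored. Unit columns in the strength file may be given as
#' `amount_unit` etc. unit strings.
#'
#' @param concept_file,relationship_file,strength_file file paths;
#'   `strength_file` may be `NULL`
#' @param config a [graph_config()]
#' @return a `concept_graph`
#' @export
load_athena_tables <- function(concept_file, relationship_file,
                               strength_file = NULL, config = graph_config()) {
  read_tsv <- function(path) {
    utils::read.delim(path, quote = "", sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                      check.names = TRUE)
  }
  concepts <- read_tsv(concept_file)
  relationships <- read_tsv(relationship_file)
  strengths <- if (!is.null(strength_file)) read_tsv(strength_file) else NULL
  rx_log("info", "loaded ", nrow(concepts), " concepts, ",
         nrow(relationships), " relationships, ",
         if (is.null(strengths)) 0 else nrow(strengths), " strength rows")
  concept_graph(concepts, relationships, strengths, config)
}

#' Persist / restore a concept graph as a single-file local store
#'
#' @param graph a `concept_graph`
#' @param path file path of the store
#' @return `load_graph` returns the restored `concept_graph`
#' @export
save_graph <- function(graph, path) {
  stopifnot(inherits(graph, "concept_graph"))
  saveRDS(list(concepts = graph$concepts, relationships = graph$relationships,
               strengths = graph$strengths, config = graph$config), path)
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path) {
  x <- readRDS(path)
  concept_graph(x$concepts, x$relationships, x$strengths, x$config)
}

has_concept <- function(graph, concept_id) {
  concept_id %in% graph$ids
}

assert_concept <- function(graph, concept_id) {
  if (length(concept_id) != 1 || is.na(concept_id) ||
      !has_concept(graph, concept_id)) {
    lookup_error(paste0("unknown concept_id: ", concept_id))
  }
  invisible(as.integer(concept_id))
}

#' Retrieve concept rows by id
#'
#' @param graph a `concept_graph`
#' @param concept_ids integer vector
#' @return data.frame of concept rows in the order given
#' @export
concept <- function(graph, concept_ids) {
  graph$concepts[match(as.integer(concept_ids), graph$ids), , drop = FALSE]
}

concept_class_of <- function(graph, concept_ids) {
  graph$concepts$concept_class_id[match(as.integer(concept_ids), graph$ids)]
}

concept_name_of <- function(graph, concept_ids) {
  graph$concepts$concept_name[match(as.integer(concept_ids), graph$ids)]
}

#' Find concepts by vocabulary-local code
#'
#' @param graph a `concept_graph`
#' @param code concept code (e.g. an ATC code or CAS registry number)
#' @param vocabulary_id optional vocabulary restriction
#' @return integer vector of concept ids (possibly empty)
#' @export
concepts_by_code <- function(graph, code, vocabulary_id = NULL) {
  if (is.null(vocabulary_id)) {
    graph$concepts$concept_id[graph$concepts$concept_code == code]
  } else {
    key <- paste(vocabulary_id, code, sep = "\r")
    graph$concepts$concept_id[graph$code_key == key]
  }
}

related_ids <- function(graph, concept_id, relationship_id) {
  rows <- graph$out_rows[[as.character(concept_id)]]
  if (is.null(rows)) return(integer())
  rel <- graph$relationships[rows, , drop = FALSE]
  sort(unique(rel$concept_id_2[rel$relationship_id %in% relationship_id]))
}

related_in_ids <- function(graph, concept_id, relationship_id) {
  rows <- graph$in_rows[[as.character(concept_id)]]
  if (is.null(rows)) return(integer())
  rel <- graph$relationships[rows, , drop = FALSE]
  sort(unique(rel$concept_id_1[rel$relationship_id %in% relationship_id]))
}

#' Concepts reachable by exactly one edge of a given relationship type
#'
#' @param graph a `concept_graph`
#' @param concept_id source concept (must exist)
#' @param relationship_id relationship type(s) to follow
#' @return data.frame of target concept rows (zero rows when none)
#' @export
related <- function(graph, concept_id, relationship_id) {
  assert_concept(graph, concept_id)
  concept(graph, related_ids(graph, concept_id, relationship_id))
}

resolve_standard_ids <- function(graph, concept_id) {
  row <- concept(graph, concept_id)
  if (isTRUE(row$standard_concept)) return(as.integer(concept_id))
  targets <- related_ids(graph, concept_id, graph$config$rel_maps_to)
  if (!length(targets)) return(integer())
  std <- targets[concept(graph, targets)$standard_concept]
  sort(std)
}

#' Resolve a concept to its standard counterpart(s)
#'
#' A standard concept resolves to itself; a non-standard concept follows its
#' maps-to edges to standard concepts (possibly none, possibly several).
#'
#' @param graph a `concept_graph`
#' @param concept_id concept to resolve (must exist)
#' @return data.frame of standard concept rows
#' @export
resolve_standard <- function(graph, concept_id) {
  assert_concept(graph, concept_id)
  concept(graph, resolve_standard_ids(graph, concept_id))
}

ancestor_ids <- function(graph, concept_id) {
  visited <- as.integer(concept_id)
  frontier <- visited
  while (length(frontier)) {
    nxt <- unlist(graph$up[as.character(frontier)], use.names = FALSE)
    nxt <- setdiff(nxt, visited)
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  sort(visited)
}

descendant_ids <- function(graph, concept_id) {
  visited <- as.integer(concept_id)
  frontier <- visited
  while (length(frontier)) {
    nxt <- unlist(graph$down[as.character(frontier)], use.names = FALSE)
    nxt <- setdiff(nxt, visited)
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  sort(visited)
}

#' Ancestors of a concept in the drug hierarchy
#'
#' Reflexive transitive closure over the configured hierarchy relationship
#' types (is-a, component/tradename/quantified/box/pack containment and
#' ingredient links). Cycle-safe: traversal uses a visited set.
#'
#' @param graph a `concept_graph`
#' @param concept_id concept (must exist)
#' @return data.frame of ancestor concept rows, including the concept itself
#' @export
ancestors <- function(graph, concept_id) {
  assert_concept(graph, concept_id)
  concept(graph, ancestor_ids(graph, concept_id))
}

#' Finest common ancestors of two concepts
#'
#' Intersects the ancestor closures of `a` and `b` and keeps the members of
#' maximal granularity rank (see [granularity_order()]); concepts whose class
#' carries no rank (non-drug classes) are ignored unless nothing ranked is
#' shared. An empty result signals that the two concepts share no drug
#' hierarchy ancestry.
#'
#' @param graph a `concept_graph`
#' @param a,b concept ids (must exist)
#' @return data.frame of common-ancestor concept rows of maximal rank,
#'   ordered by concept id
#' @export
finest_common_ancestors <- function(graph, a, b) {
  assert_concept(graph, a)
  assert_concept(graph, b)
  common <- intersect(ancestor_ids(graph, a), ancestor_ids(graph, b))
  if (!length(common)) return(concept(graph, integer()))
  ranks <- granularity_rank(concept_class_of(graph, common))
  if (all(is.na(ranks))) return(concept(graph, integer()))
  best <- common[!is.na(ranks) & ranks == max(ranks, na.rm = TRUE)]
  concept(graph, sort(best))
}

#' @export
print.concept_graph <- function(x, ...) {
  cat("<concept_graph> ", nrow(x$concepts), " concepts, ",
      nrow(x$relationships), " relationships, ",
      nrow(x$strengths), " strength rows\n", sep = "")
  cls <- sort(table(x$concepts$concept_class_id), decreasing = TRUE)
  cat("  classes: ", paste0(names(cls), " (", cls, ")", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

strength_rows_of <- function(graph, drug_concept_id) {
  rows <- graph$strength_rows[[as.character(drug_concept_id)]]
  if (is.null(rows)) return(graph$strengths[0, , drop = FALSE])
  graph$strengths[rows, , drop = FALSE]
}
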