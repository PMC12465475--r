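# Usagi-style CSV interchange, preservation of reviewer-approved rows across
# re-executions, and conversion to HL7 FHIR ConceptMap resources (R4B and
# R5).
#
# Usagi dialect (the package's canonical column set, importable by the Usagi
# review tool): comma-separated, quoted strings, columns source_code,
# source_concept_id, source_vocabulary_id, source_code_description,
# target_concept_id, target_vocabulary_id, mapping_status, equivalence,
# match_score, comment, created_by, created_on, status_set_by, status_set_on.

USAGI_COLUMNS <- c("source_code", "source_concept_id", "source_vocabulary_id",
                   "source_code_description", "target_concept_id",
                   "target_vocabulary_id", "mapping_status", "equivalence",
                   "match_score", "comment", "created_by", "created_on",
                   "status_set_by", "status_set_on")

MAPPING_STATUSES <- c("UNCHECKED", "APPROVED", "FLAGGED", "IGNORED")
EQUIVALENCE_HINTS <- c("EQUAL", "WIDER", "NARROWER", "RELATED", "UNMATCHED")

sort_mapping_rows <- function(rows) {
  rows[order(rows$source_code, rows$target_concept_id, method = "radix"), ,
       drop = FALSE]
}

#' Write mapping rows as a Usagi-style CSV
#'
#' One line per (source code, target concept) pair -- a multi-target mapping
#' emits multiple lines -- in stable (source code, target id) order, so that
#' repeated runs on identical inputs produce byte-identical files. The
#' timestamp columns are left empty for the same reason.
#'
#' @param rows mapping-row data.frame (see [finalize()])
#' @param path output path
#' @param source_vocabulary_id label for the source vocabulary column
#' @return invisibly, the path
#' @export
write_usagi <- function(rows, path, source_vocabulary_id = "SOURCE") {
  rows <- sort_mapping_rows(rows)
  n <- nrow(rows)
  df <- data.frame(
    source_code = rows$source_code,
    source_concept_id = rep(0L, n),
    source_vocabulary_id = rep(source_vocabulary_id, n),
    source_code_description = rows$source_name,
    target_concept_id = rows$target_concept_id,
    target_vocabulary_id = rows$target_vocabulary_id,
    mapping_status = rows$status,
    equivalence = rows$equivalence_hint,
    match_score = rows$match_score,
    comment = rows$comment,
    created_by = rows$created_by,
    created_on = rep("", n),
    status_set_by = rows$status_set_by,
    status_set_on = rep("", n),
    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, na = "", quote = TRUE,
                   eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a Usagi-style CSV back into mapping rows
#'
#' Columns beyond the canonical dialect are preserved opaquely by appending
#' `name=value` pairs to the comment field. Missing mandatory columns raise
#' a format error. Status and equivalence values outside the modeled
#' enumerations are kept as-is with a warning.
#'
#' @param path CSV path
#' @return mapping-row data.frame
#' @export
read_usagi <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", colClasses = "character")
  mandatory <- c("source_code", "target_concept_id", "mapping_status",
                 "equivalence", "match_score")
  miss <- setdiff(mandatory, names(df))
  if (length(miss)) format_error(paste0("Usagi file lacks column(s): ",
                                        paste(miss, collapse = ", ")))
  get <- function(col, default = "") if (col %in% names(df)) df[[col]] else
    rep(default, nrow(df))
  comment <- get("comment")
  extras <- setdiff(names(df), USAGI_COLUMNS)
  for (col in extras) {
    has <- nzchar(df[[col]])
    comment[has] <- paste0(comment[has], " [", col, "=", df[[col]][has], "]")
  }
  bad <- !df$mapping_status %in% MAPPING_STATUSES
  if (any(bad)) rx_log("warn", "unrecognized mapping_status value(s): ",
                       paste(unique(df$mapping_status[bad]), collapse = ", "))
  out <- data.frame(
    source_code = df$source_code,
    source_name = get("source_code_description"),
    target_concept_id = as.integer(df$target_concept_id),
    target_vocabulary_id = get("target_vocabulary_id"),
    target_class = rep("", nrow(df)),
    match_score = as.numeric(df$match_score),
    status = df$mapping_status,
    equivalence_hint = df$equivalence,
    comment = trimws(comment),
    created_by = get("created_by"),
    status_set_by = get("status_set_by"),
    stringsAsFactors = FALSE)
  sort_mapping_rows(out)
}

#' Merge a new mapping run with a previous reviewed one
#'
#' For every source code whose previous rows carry reviewer status
#' `APPROVED` or `IGNORED`, the previous rows replace the new ones verbatim
#' (reviewer work persists across re-executions); all other source codes
#' take the new result, so unreviewed rows from earlier runs never
#' resurface.
#'
#' @param new_rows,previous_rows mapping-row data.frames
#' @return merged mapping-row data.frame in stable order
#' @export
merge_previous <- function(new_rows, previous_rows) {
  if (is.null(previous_rows) || !nrow(previous_rows)) {
    return(sort_mapping_rows(new_rows))
  }
  reviewed <- unique(previous_rows$source_code[
    previous_rows$status %in% c("APPROVED", "IGNORED")])
  keep_prev <- previous_rows[previous_rows$source_code %in% reviewed, ,
                             drop = FALSE]
  keep_new <- new_rows[!new_rows$source_code %in% reviewed, , drop = FALSE]
  sort_mapping_rows(rbind(keep_new, keep_prev))
}

R4B_EQUIVALENCE <- c(EQUAL = "equivalent", NARROWER = "narrower",
                     WIDER = "wider", RELATED = "relatedto",
                     UNMATCHED = "unmatched")
R5_RELATIONSHIP <- c(EQUAL = "equivalent",
                     NARROWER = "source-is-narrower-than-target",
                     WIDER = "source-is-broader-than-target",
                     RELATED = "related-to",
                     UNMATCHED = "not-related-to")

#' Convert mapping rows to a FHIR ConceptMap resource
#'
#' Builds an R4B or R5 ConceptMap as a nested list ready for JSON
#' serialization. One group is emitted per target code system; every mapped
#' row appears exactly once as an element target, with the equivalence hint
#' translated to the release's code set (R4B `equivalence`, R5
#' `relationship`). Unmapped rows are emitted per release convention: an
#' `unmatched` target without code in R4B, `noMap` in R5.
#'
#' @param rows mapping-row data.frame
#' @param release `"R4B"` or `"R5"`
#' @param source_system source code system URI
#' @param target_systems named character vector: target vocabulary id ->
#'   code system URI
#' @param graph optional `concept_graph` used to attach target display names
#' @return list of class `conceptmap` (attribute `release`)
#' @export
to_conceptmap <- function(rows, release = c("R4B", "R5"),
                          source_system = "urn:example:source-drug-codes",
                          target_systems = c(
                            "RxNorm" = "http://www.nlm.nih.gov/research/umls/rxnorm",
                            "RxNorm Extension" = "urn:omop:rxnorm-extension"),
                          graph = NULL) {
  if (!is.character(release) || !release[1] %in% c("R4B", "R5")) {
    argument_error("release must be \"R4B\" or \"R5\"")
  }
  release <- release[1]
  if (!nrow(rows)) argument_error("no mapping rows to convert")
  rows <- sort_mapping_rows(rows)
  r5 <- identical(release, "R5")
  mapped <- rows[rows$target_concept_id > 0, , drop = FALSE]
  unmapped <- rows[rows$target_concept_id == 0, , drop = FALSE]

  target_of <- function(row) {
    code_set <- if (r5) R5_RELATIONSHIP else R4B_EQUIVALENCE
    hint <- if (row$equivalence_hint %in% names(code_set))
      code_set[[row$equivalence_hint]] else code_set[["RELATED"]]
    tgt <- list(code = as.character(row$target_concept_id))
    if (!is.null(graph) && has_concept(graph, row$target_concept_id)) {
      tgt$display <- concept_name_of(graph, row$target_concept_id)
    }
    if (r5) tgt$relationship <- hint else tgt$equivalence <- hint
    if (nzchar(row$comment)) tgt$comment <- row$comment
    tgt
  }

  groups <- list()
  vocabs <- unique(mapped$target_vocabulary_id)
  for (v in vocabs) {
    sub <- mapped[mapped$target_vocabulary_id == v, , drop = FALSE]
    elements <- lapply(split(sub, sub$source_code), function(s) {
      el <- list(code = s$source_code[1])
      if (nzchar(s$source_name[1])) el$display <- s$source_name[1]
      el$target <- lapply(seq_len(nrow(s)), function(i) target_of(s[i, ]))
      el
    })
    tgt_uri <- if (v %in% names(target_systems)) target_systems[[v]] else
      paste0("urn:rxnemap:vocabulary:", gsub("[^A-Za-z0-9]+", "-", v))
    groups[[length(groups) + 1]] <- list(
      source = source_system, target = tgt_uri,
      element = unname(elements[c_sort(names(elements))]))
  }
  if (nrow(unmapped)) {
    elements <- lapply(split(unmapped, unmapped$source_code), function(s) {
      el <- list(code = s$source_code[1])
      if (nzchar(s$source_name[1])) el$display <- s$source_name[1]
      if (r5) el$noMap <- TRUE
      else el$target <- list(list(equivalence = "unmatched"))
      el
    })
    groups[[length(groups) + 1]] <- list(
      source = source_system,
      element = unname(elements[c_sort(names(elements))]))
  }
  doc <- list(
    resourceType = "ConceptMap",
    status = "active",
    group = groups)
  if (r5) {
    doc <- append(doc, list(
      sourceScopeUri = source_system,
      targetScopeUri = unname(target_systems[1])), after = 2)
  } else {
    doc <- append(doc, list(
      sourceUri = source_system,
      targetUri = unname(target_systems[1])), after = 2)
  }
  structure(doc, class = c("conceptmap", "list"), release = release)
}

#' Structurally validate a ConceptMap resource
#'
#' Checks the release-specific structural rules this package relies on:
#' resource type and status, group source presence, non-empty element lists,
#' element codes, and -- per element target -- a code plus an `equivalence`
#' (R4B) or `relationship` (R5) value from the release's code set; R5
#' elements may instead declare `noMap`, R4B elements an `unmatched` target
#' without code.
#'
#' @param doc a list as produced by [to_conceptmap()] (or parsed from JSON)
#' @param release `"R4B"` or `"R5"`
#' @return character vector of problems; empty when the document passes
#' @export
validate_conceptmap <- function(doc, release = attr(doc, "release") %||% "R4B") {
  problems <- character()
  say <- function(...) problems <<- c(problems, paste0(...))
  r5 <- identical(release, "R5")
  if (!identical(doc$resourceType, "ConceptMap")) say("resourceType must be ConceptMap")
  if (is.null(doc$status)) say("status is required")
  if (!length(doc$group)) say("at least one group is required")
  codes <- if (r5) unname(R5_RELATIONSHIP) else unname(R4B_EQUIVALENCE)
  for (gi in seq_along(doc$group)) {
    g <- doc$group[[gi]]
    if (is.null(g$source)) say("group ", gi, ": source system missing")
    if (!length(g$element)) say("group ", gi, ": empty element list")
    for (ei in seq_along(g$element)) {
      el <- g$element[[ei]]
      if (is.null(el$code)) say("group ", gi, " element ", ei, ": code missing")
      if (isTRUE(el$noMap)) {
        if (!r5) say("group ", gi, " element ", ei, ": noMap is R5-only")
        if (length(el$target)) say("group ", gi, " element ", ei,
                                   ": noMap excludes targets")
        next
      }
      if (!length(el$target)) {
        if (r5) say("group ", gi, " element ", ei, ": target or noMap required")
        next
      }
      for (ti in seq_along(el$target)) {
        t <- el$target[[ti]]
        rel <- if (r5) t$relationship else t$equivalence
        if (is.null(rel)) {
          say("group ", gi, " element ", ei, " target ", ti,
              if (r5) ": relationship missing" else ": equivalence missing")
        } else if (!rel %in% codes) {
          say("group ", gi, " element ", ei, " target ", ti,
              ": code '", rel, "' not in ", release, " value set")
        }
        if (is.null(t$code) && !identical(t$equivalence, "unmatched")) {
          say("group ", gi, " element ", ei, " target ", ti, ": code missing")
        }
      }
    }
  }
  problems
}

#' Serialize a ConceptMap to JSON
#'
#' @param doc a `conceptmap`
#' @param path output path
#' @return invisibly, the path
#' @export
write_conceptmap <- function(doc, path) {
  jsonlite::write_json(unclass(doc), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
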