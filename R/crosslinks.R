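# Supplementary bridge tables: substance translations/synonyms (shared-id
# groups with a designated preferred English name), German substance name ->
# CAS registry number, EDQM dose form -> RxN/E dose form alignment, and EU
# registration number -> EDQM dose form (pre-extracted from product
# information sheets).
#
# CSV schemas (comma-separated, UTF-8, header row):
#   translations:            shared_id, language, name, preferred (1/0)
#   cas:                     german_name, cas_number
#   doseform_alignment:      edqm_term, rxne_concept_id
#   registration_doseforms:  eu_registration, edqm_term

CAS_PATTERN <- "^[0-9]{2,7}-[0-9]{2}-[0-9]$"

#' Load the supplementary cross-link tables
#'
#' All name lookups over these tables are case- and punctuation-insensitive:
#' they use the same normalization as ingredient synonym matching
#' ([norm_name()]). CAS rows whose registry number does not match the
#' `NNNNNNN-NN-N` check format are rejected at load with a warning. When a
#' concept graph is supplied, alignment targets are checked to exist and be
#' of class Dose Form; offending rows are dropped with a warning.
#'
#' @param translation_file,cas_file,alignment_file,registration_file CSV
#'   paths; any may be `NULL` to leave that table empty
#' @param graph optional `concept_graph` for referential integrity checks
#' @return object of class `crosslinks`
#' @export
load_crosslinks <- function(translation_file = NULL, cas_file = NULL,
                            alignment_file = NULL, registration_file = NULL,
                            graph = NULL) {
  read <- function(path, need) {
    if (is.null(path)) {
      return(as.data.frame(sapply(need, function(x) character(),
                                  simplify = FALSE), stringsAsFactors = FALSE))
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", colClasses = "character")
    miss <- setdiff(need, names(df))
    if (length(miss)) format_error(paste0(basename(path), " lacks column(s): ",
                                          paste(miss, collapse = ", ")))
    df
  }
  tr <- read(translation_file, c("shared_id", "language", "name"))
  if (is.null(tr$preferred)) tr$preferred <- "0"
  cas <- read(cas_file, c("german_name", "cas_number"))
  bad <- !grepl(CAS_PATTERN, cas$cas_number)
  if (any(bad)) {
    rx_log("warn", sum(bad), " CAS row(s) with malformed registry number rejected")
    cas <- cas[!bad, , drop = FALSE]
  }
  al <- read(alignment_file, c("edqm_term", "rxne_concept_id"))
  al$rxne_concept_id <- as.integer(al$rxne_concept_id)
  if (!is.null(graph) && nrow(al)) {
    ok <- al$rxne_concept_id %in% graph$ids &
      concept_class_of(graph, al$rxne_concept_id) == "Dose Form"
    ok[is.na(ok)] <- FALSE
    if (any(!ok)) {
      rx_log("warn", sum(!ok), " alignment row(s) with unknown or non-dose-form ",
             "target dropped")
      al <- al[ok, , drop = FALSE]
    }
  }
  reg <- read(registration_file, c("eu_registration", "edqm_term"))
  structure(list(
    translations = tr,
    cas = cas,
    alignment = al,
    registration = reg,
    tr_key = norm_name(tr$name),
    cas_key = norm_name(cas$german_name),
    al_key = norm_name(al$edqm_term),
    reg_key = toupper(trimws(reg$eu_registration))
  ), class = "crosslinks")
}

#' @export
print.crosslinks <- function(x, ...) {
  cat("<crosslinks> ", nrow(x$translations), " translation rows, ",
      nrow(x$cas), " CAS rows, ", nrow(x$alignment), " dose-form alignments, ",
      nrow(x$registration), " registration dose forms\n", sep = "")
  invisible(x)
}

#' Translate a substance name to its English form(s)
#'
#' Finds every translation-table entry whose normalized name matches, then
#' returns all English-language names (including the designated preferred
#' name) sharing an identifier with any of them. Matching is performed
#' across all languages of a shared-id group.
#'
#' @param links a `crosslinks`
#' @param name substance name in any language
#' @return character vector of English names (empty when unknown)
#' @export
translate <- function(links, name) {
  key <- norm_name(name)
  if (!nzchar(key)) return(character())
  ids <- unique(links$translations$shared_id[links$tr_key == key])
  if (!length(ids)) return(character())
  tr <- links$translations
  hit <- tr$shared_id %in% ids &
    (tolower(tr$language) %in% c("en", "english") | tr$preferred %in% c("1", "TRUE"))
  c_sort(unique(tr$name[hit]))
}

#' Look up CAS registry numbers for a (German) substance name
#'
#' @param links a `crosslinks`
#' @param name substance name
#' @return character vector of CAS numbers (empty when none)
#' @export
cas_lookup <- function(links, name) {
  key <- norm_name(name)
  if (!nzchar(key)) return(character())
  c_sort(unique(links$cas$cas_number[links$cas_key == key]))
}

#' Dose-form concepts for an EU registration number
#'
#' Two-hop composition: registration number -> EDQM dose form term(s)
#' (extracted from the product information sheet) -> aligned RxN/E dose form
#' concept(s). Empty when either hop is missing.
#'
#' @param links a `crosslinks`
#' @param eu_registration a single normalized registration number
#' @return integer vector of dose-form concept ids
#' @export
doseforms_for_registration <- function(links, eu_registration) {
  key <- toupper(trimws(eu_registration))
  if (!nzchar(key)) return(integer())
  terms <- unique(links$registration$edqm_term[links$reg_key == key])
  if (!length(terms)) return(integer())
  hits <- links$al_key %in% norm_name(terms)
  sort(unique(links$alignment$rxne_concept_id[hits]))
}
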