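# Source terminology model: one national drug product per row, with
# per-ingredient strengths, ATC references, optional EU registration and a
# quantity supplement (box size, total volume/actuations) joined by source
# code.
#
# Source CSV schema (comma-separated, UTF-8, header row):
#   pzn                 unique source code
#   name                product name
#   registration_status free-text status
#   dose_form           source-language dose form text (optional)
#   atc_codes           ';'-separated ATC codes (optional)
#   eu_registration     EU registration number, possibly a range (optional)
#   ingredients         ';'-separated entries "name|strength|unit|active";
#                       strength/unit may be empty, active is 1/0
#   box_size, total_value, total_unit   optional; usually supplied by the
#                       supplement table instead
#
# Supplement CSV schema: pzn, box_size, total_value, total_unit.
#
# A national export with a different layout is adapted by passing a custom
# `ingredient_parser` and/or reshaping ahead of load_source(); the model is
# deliberately decoupled from any particular national file dialect.

#' Construct a source ingredient
#'
#' @param raw_name ingredient name as distributed (non-empty)
#' @param strength_value,strength_unit optional strength
#' @param active is this an active ingredient (excipients are dropped by the
#'   loader)
#' @param synonyms additional known synonyms; the raw name and its trivial
#'   text variations are always included (see [expand_synonyms()])
#' @return object of class `source_ingredient`
#' @export
source_ingredient <- function(raw_name, strength_value = NA_real_,
                              strength_unit = NA_character_, active = TRUE,
                              synonyms = character()) {
  stopifnot(is.character(raw_name), length(raw_name) == 1, nzchar(raw_name))
  ing <- structure(list(
    raw_name = raw_name,
    strength_value = as.numeric(strength_value),
    strength_unit = as.character(strength_unit),
    active = isTRUE(active),
    synonyms = character()
  ), class = "source_ingredient")
  expand_synonyms(ing, synonyms)
}

#' Construct a source drug product
#'
#' @param pzn source code (unique within a dataset)
#' @param name product name
#' @param ingredients list of [source_ingredient()]s
#' @param registration_status free-text status
#' @param dose_form source-language dose form text
#' @param atc_codes character vector of ATC codes
#' @param eu_registration raw registration string (possibly a range); the
#'   normalized individual numbers are stored in `eu_registrations`
#' @param box_size units per marketed box
#' @param total_value,total_unit total size of a liquid/gas formulation or
#'   number of actuations
#' @return object of class `source_drug`
#' @export
source_drug <- function(pzn, name, ingredients = list(),
                        registration_status = NA_character_,
                        dose_form = NA_character_,
                        atc_codes = character(),
                        eu_registration = NA_character_,
                        box_size = NA_integer_,
                        total_value = NA_real_, total_unit = NA_character_) {
  stopifnot(nzchar(pzn))
  regs <- if (!is.na(eu_registration)) normalize_eu_registration(eu_registration)
          else character()
  structure(list(
    pzn = as.character(pzn),
    name = as.character(name),
    registration_status = registration_status,
    dose_form = dose_form,
    ingredients = ingredients,
    atc_codes = atc_codes[nzchar(atc_codes)],
    eu_registration = eu_registration,
    eu_registrations = regs,
    box_size = if (is.na(box_size)) NA_integer_ else as.integer(box_size),
    total_value = as.numeric(total_value),
    total_unit = as.character(total_unit)
  ), class = "source_drug")
}

#' @export
print.source_drug <- function(x, ...) {
  cat("<source_drug> ", x$pzn, " ", x$name, "\n  ingredients: ",
      paste(vapply(x$ingredients, function(i)
        paste0(i$raw_name,
               if (!is.na(i$strength_value))
                 paste0(" ", i$strength_value, " ", i$strength_unit) else ""),
        ""), collapse = "; "), "\n", sep = "")
  invisible(x)
}

# default parser for the packed ingredients column
parse_ingredient_field <- function(field, pzn = "?") {
  field <- trimws(field %||% "")
  if (is.na(field) || !nzchar(field)) return(list())
  entries <- strsplit(field, ";", fixed = TRUE)[[1]]
  out <- list()
  for (e in entries) {
    parts <- strsplit(e, "|", fixed = TRUE)[[1]]
    length(parts) <- 4
    nm <- trimws(parts[1])
    if (is.na(nm) || !nzchar(nm)) next
    sv <- suppressWarnings(as.numeric(parts[2]))
    if (!is.na(parts[2]) && nzchar(trimws(parts[2])) && is.na(sv)) {
      rx_log("warn", "drug ", pzn, ": malformed strength '", parts[2],
             "' for ingredient '", nm, "'; strength left absent")
    }
    su <- trimws(parts[3])
    if (is.na(su) || !nzchar(su)) su <- NA_character_
    if (is.na(sv)) su <- su  # unit kept even without value (rarely useful)
    active <- is.na(parts[4]) || trimws(parts[4]) != "0"
    out[[length(out) + 1]] <- source_ingredient(nm, sv, su, active)
  }
  out
}

#' Load the source terminology and its quantity supplement
#'
#' Reads the source CSV (one drug product per row) and joins the optional
#' supplement table on the source code. Excipients (`active = 0` entries of
#' the ingredient field) are dropped; drugs without any active ingredient
#' are kept with a warning. Supplement rows without a matching source row
#' are logged and excluded. Box size and total size in the main table take
#' precedence over the supplement.
#'
#' @param source_file path to the source CSV
#' @param supplement_file optional path to the supplement CSV
#' @param ingredient_parser function `(field, pzn) -> list of
#'   source_ingredient`, the adapter for the packed ingredient column
#' @return list of [source_drug()]s
#' @export
load_source <- function(source_file, supplement_file = NULL,
                        ingredient_parser = parse_ingredient_field) {
  src <- utils::read.csv(source_file, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", colClasses = "character")
  need <- c("pzn", "name", "ingredients")
  miss <- setdiff(need, names(src))
  if (length(miss)) format_error(paste0("source table lacks column(s): ",
                                        paste(miss, collapse = ", ")))
  if (anyDuplicated(src$pzn)) {
    integrity_error(paste0("duplicate pzn: ",
      paste(unique(src$pzn[duplicated(src$pzn)]), collapse = ", ")))
  }
  opt <- function(col, i) if (col %in% names(src) && nzchar(src[[col]][i] %||% ""))
    src[[col]][i] else NA_character_
  supp <- NULL
  if (!is.null(supplement_file)) {
    supp <- utils::read.csv(supplement_file, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8", colClasses = "character")
    if (!"pzn" %in% names(supp)) format_error("supplement table lacks column: pzn")
    unmatched <- setdiff(supp$pzn, src$pzn)
    if (length(unmatched)) {
      rx_log("warn", length(unmatched), " supplement row(s) without source row ",
             "excluded: ", paste(utils::head(unmatched, 5), collapse = ", "))
    }
  }
  drugs <- vector("list", nrow(src))
  for (i in seq_len(nrow(src))) {
    ings <- ingredient_parser(src$ingredients[i], src$pzn[i])
    actives <- Filter(function(x) isTRUE(x$active), ings)
    if (!length(actives)) {
      rx_log("warn", "drug ", src$pzn[i], " has no active ingredient")
    }
    atc <- opt("atc_codes", i)
    atc <- if (is.na(atc)) character() else
      trimws(strsplit(atc, ";", fixed = TRUE)[[1]])
    box <- suppressWarnings(as.integer(opt("box_size", i)))
    tv <- suppressWarnings(as.numeric(opt("total_value", i)))
    tu <- opt("total_unit", i)
    if (!is.null(supp)) {
      j <- match(src$pzn[i], supp$pzn)
      if (!is.na(j)) {
        if (is.na(box)) box <- suppressWarnings(as.integer(supp$box_size[j] %||% NA))
        if (is.na(tv) && "total_value" %in% names(supp)) {
          tv <- suppressWarnings(as.numeric(supp$total_value[j]))
          tu <- if ("total_unit" %in% names(supp)) supp$total_unit[j] else NA_character_
          if (!is.na(tu) && !nzchar(tu)) tu <- NA_character_
        }
      }
    }
    drugs[[i]] <- source_drug(
      pzn = src$pzn[i], name = src$name[i], ingredients = actives,
      registration_status = opt("registration_status", i),
      dose_form = opt("dose_form", i),
      atc_codes = atc,
      eu_registration = opt("eu_registration", i),
      box_size = box, total_value = tv, total_unit = tu)
  }
  rx_log("info", "loaded ", length(drugs), " source drugs from ", source_file)
  drugs
}

#' Serialize source drugs back to the source CSV schema
#'
#' Inverse of [load_source()] on the modeled fields (ingredients are packed
#' back into the `name|strength|unit|active` entry format), so that a loaded
#' dataset round-trips.
#'
#' @param drugs list of [source_drug()]s
#' @param path output CSV path
#' @return invisibly, the path
#' @export
write_source <- function(drugs, path) {
  pack <- function(d) paste(vapply(d$ingredients, function(i) paste(
    i$raw_name,
    if (is.na(i$strength_value)) "" else format(i$strength_value, scientific = FALSE),
    if (is.na(i$strength_unit)) "" else i$strength_unit,
    if (i$active) "1" else "0", sep = "|"), ""), collapse = ";")
  df <- data.frame(
    pzn = vapply(drugs, `[[`, "", "pzn"),
    name = vapply(drugs, `[[`, "", "name"),
    registration_status = vapply(drugs, function(d) d$registration_status %||% NA_character_, ""),
    dose_form = vapply(drugs, function(d) d$dose_form %||% NA_character_, ""),
    atc_codes = vapply(drugs, function(d) paste(d$atc_codes, collapse = ";"), ""),
    eu_registration = vapply(drugs, function(d) d$eu_registration %||% NA_character_, ""),
    ingredients = vapply(drugs, pack, ""),
    box_size = vapply(drugs, function(d) as.integer(d$box_size), 1L),
    total_value = vapply(drugs, function(d) as.numeric(d$total_value), 1),
    total_unit = vapply(drugs, function(d) d$total_unit %||% NA_character_, ""),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

active_ingredients <- function(drug) {
  Filter(function(x) isTRUE(x$active), drug$ingredients)
}
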