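# Shared text normalization. Every name comparison in the package (ingredient
# index lookups, translation and CAS table lookups, dose-form alignment)
# funnels through norm_name() so that the modules agree on what counts as
# "the same name".

UMLAUT_MAP <- c("ä" = "ae", "ö" = "oe", "ü" = "ue",
                "ß" = "ss",
                "Ä" = "Ae", "Ö" = "Oe", "Ü" = "Ue")

# single-character diacritic folding (covers the Latin-1 letters that occur
# in European substance names)
DIACRITIC_FROM <- "áàâãåæçéèêëíìîïñóòôõøúùûýÿ"
DIACRITIC_TO   <- "aaaaaaceeeeiiiinooooouuuyy"

transliterate <- function(x) {
  for (i in seq_along(UMLAUT_MAP)) {
    x <- gsub(names(UMLAUT_MAP)[i], UMLAUT_MAP[[i]], x, fixed = TRUE)
  }
  chartr(DIACRITIC_FROM, DIACRITIC_TO, x)
}

#' Normalize a name for matching
#'
#' Lower-cases, transliterates German umlauts and sharp s (a -> ae, o -> oe,
#' u -> ue, ss), folds other Latin diacritics, replaces every
#' non-alphanumeric run by a single space and trims. All cross-vocabulary
#' name matching in the package compares `norm_name()` values, so
#' "Zinksulfat-Heptahydrat" and "zinksulfat heptahydrat" are the same key.
#'
#' @param x character vector
#' @return character vector of normalized keys (possibly empty strings)
#' @export
norm_name <- function(x) {
  x <- transliterate(as.character(x))
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

# one round of trivial text variations on a character vector
variation_step <- function(x) {
  out <- c(
    x,
    tolower(x),
    transliterate(x),
    gsub(" ", "-", x, fixed = TRUE),
    gsub("-", " ", x, fixed = TRUE),
    gsub("[^[:alnum:] -]+", "", x)
  )
  out <- gsub("[ ]+", " ", out)
  out <- trimws(out)
  unique(out[nzchar(out)])
}

#' Expand an ingredient's synonym set with trivial text variations
#'
#' Applies a fixed, order-independent rule set -- case folding, space/hyphen
#' swap, stripping of other non-alphanumeric characters, umlaut and diacritic
#' transliteration, whitespace collapsing -- to closure: the returned set is
#' stable under a second application (idempotent). The original strings are
#' always retained and the empty string is never produced.
#'
#' @param ing a `source_ingredient` (see [source_ingredient()]) or a
#'   character vector of names
#' @param extra_synonyms additional synonyms to seed the expansion with
#' @return the ingredient with its `synonyms` field expanded, or (for a
#'   character input) the expanded character set
#' @export
expand_synonyms <- function(ing, extra_synonyms = character()) {
  if (is.character(ing)) {
    return(close_variations(unique(c(ing, extra_synonyms))))
  }
  stopifnot(inherits(ing, "source_ingredient"))
  ing$synonyms <- close_variations(unique(c(ing$raw_name, ing$synonyms,
                                            extra_synonyms)))
  ing
}

close_variations <- function(seed, max_iter = 10L) {
  cur <- unique(seed[nzchar(seed)])
  for (i in seq_len(max_iter)) {
    nxt <- unique(c(cur, variation_step(cur)))
    if (length(nxt) == length(cur)) break
    cur <- nxt
  }
  c_sort(cur)
}

#' Normalize an EU drug registration number, expanding ranges
#'
#' Source terminologies sometimes list a span of registration numbers as a
#' range over the final segment ("EU/16/1157/003-004", with either a hyphen
#' or an en dash as separator). The range is expanded into the individual
#' numbers, preserving the zero padding of the final segment; a degenerate
#' range yields a single number. Input without a range separator is returned
#' as a singleton; input whose range fails to parse (non-numeric bounds,
#' end before start) yields an empty vector with a warning.
#'
#' @param raw a single registration number string
#' @return character vector of individual registration numbers
#' @export
normalize_eu_registration <- function(raw) {
  raw <- trimws(as.character(raw))
  if (length(raw) != 1 || is.na(raw) || !nzchar(raw)) return(character())
  m <- regmatches(raw, regexec("^(.*/)([0-9]+)[-–]([0-9]+)$", raw))[[1]]
  if (length(m) == 0) return(raw)
  prefix <- m[2]; from <- m[3]; to <- m[4]
  width <- nchar(from)
  from_i <- suppressWarnings(as.integer(from))
  to_i <- suppressWarnings(as.integer(to))
  if (is.na(from_i) || is.na(to_i) || to_i < from_i) {
    rx_log("warn", "unparseable registration range: ", raw)
    return(character())
  }
  paste0(prefix, formatC(seq.int(from_i, to_i), width = width, flag = "0"))
}

#' Tokenize a drug or brand name
#'
#' Splits on every non-alphanumeric character run and lower-cases, the
#' boundary convention used by the brand prefix search.
#'
#' @param x a single string
#' @return character vector of tokens (no empty tokens)
#' @export
tokenize_name <- function(x) {
  toks <- strsplit(tolower(as.character(x)), "[^[:alnum:]]+")[[1]]
  toks[nzchar(toks)]
}
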