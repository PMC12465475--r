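# Dose-form mapping by the registration-sheet path and by probabilistic
# voting, and brand mapping by tokenized longest-common-prefix search.

#' Dose forms for a drug via its EU registration number(s)
#'
#' Union of the registration-to-EDQM-to-RxN/E composition over every
#' normalized registration number of the drug.
#'
#' @param drug a [source_drug()]
#' @param links a `crosslinks`
#' @return integer vector of dose-form concept ids
#' @export
map_doseform_by_registration <- function(drug, links) {
  sort(unique(unlist(lapply(drug$eu_registrations,
                            doseforms_for_registration, links = links),
                     use.names = FALSE)))
}

# dose forms of the RxN/E drug concepts matching one anchor concept:
# ingredient -> drugs having that ingredient; brand -> drugs carrying that
# brand name; drug component -> clinical drugs consisting of it. The dose
# form of each such drug concept is collected.
doseforms_of_anchor <- function(graph, anchor_id) {
  cfg <- graph$config
  drugs <- c(
    related_in_ids(graph, anchor_id, cfg$rel_has_ingredient),
    related_in_ids(graph, anchor_id, cfg$rel_has_brand_name),
    related_in_ids(graph, anchor_id, cfg$rel_consists_of)
  )
  forms <- unlist(lapply(unique(drugs), function(d)
    related_ids(graph, d, cfg$rel_has_dose_form)), use.names = FALSE)
  sort(unique(c(forms, related_ids(graph, anchor_id, cfg$rel_has_dose_form))))
}

#' Collect dose-form votes per source dose form
#'
#' Every drug retrieves the dose forms of the RxN/E drug concepts matching
#' its anchors (mapped ingredients, matched brand and, on the second pass,
#' clinical drug component candidates). A drug that retrieves a single form
#' votes for it with weight 1; a drug that retrieves `k` forms divides its
#' vote equally, contributing `1/k` to each. Votes accumulate per source
#' dose-form text; drugs retrieving nothing, or lacking a source dose form,
#' contribute nothing. For each tally the vote weights sum to the number of
#' contributing drugs (conservation, up to 1e-9).
#'
#' @param drugs list of [source_drug()]s
#' @param anchors named list (by pzn) of integer anchor concept ids
#' @param graph a `concept_graph`
#' @return named list of vote tallies, one per source form, each a list with
#'   `source_form`, `votes` (named numeric, names are dose-form concept
#'   ids) and `contributing_drugs`
#' @export
collect_votes <- function(drugs, anchors, graph) {
  tallies <- new.env(parent = emptyenv())
  for (drug in drugs) {
    form_txt <- drug$dose_form
    if (is.null(form_txt) || is.na(form_txt) || !nzchar(form_txt)) next
    anc <- anchors[[drug$pzn]]
    if (is.null(anc) || !length(anc)) next
    retrieved <- sort(unique(unlist(lapply(unique(anc), doseforms_of_anchor,
                                           graph = graph), use.names = FALSE)))
    if (!length(retrieved)) next
    w <- 1 / length(retrieved)
    key <- norm_name(form_txt)
    cur <- tallies[[key]] %||% list(source_form = form_txt,
                                    votes = numeric(),
                                    contributing_drugs = 0L)
    for (f in as.character(retrieved)) {
      cur$votes[f] <- (if (f %in% names(cur$votes)) cur$votes[[f]] else 0) + w
    }
    cur$contributing_drugs <- cur$contributing_drugs + 1L
    tallies[[key]] <- cur
  }
  out <- as.list(tallies)
  out[c_sort(names(out))]
}

#' Decide the mapped dose forms from a vote tally
#'
#' Accepts every dose form whose accumulated weight reaches `alpha` times
#' the maximum weight in the tally. Deterministic and scale-invariant:
#' multiplying all weights by a positive constant leaves the decision
#' unchanged. A nonempty tally always yields at least one form (the
#' maximum itself); an empty tally yields none, leaving the source form
#' unmapped.
#'
#' @param tally one tally as produced by [collect_votes()]
#' @param alpha acceptance fraction in (0, 1]
#' @return integer vector of dose-form concept ids, sorted
#' @export
decide_doseforms <- function(tally, alpha = 0.5) {
  stopifnot(alpha > 0, alpha <= 1)
  v <- tally$votes
  if (!length(v)) return(integer())
  keep <- v >= alpha * max(v) - 1e-12
  sort(as.integer(names(v)[keep]))
}

#' Match a brand by tokenized longest-common-prefix search
#'
#' Both the product name and every brand name are tokenized on runs of
#' non-alphanumeric characters and compared case-insensitively. A brand
#' matches when its complete token sequence is a prefix of the product-name
#' token sequence; among matches the one with the most tokens wins, ties
#' broken by smaller concept id. Single-token brands shorter than
#' `min_token_chars` characters are ignored to suppress spurious hits.
#'
#' @param drug_name product name string
#' @param graph a `concept_graph` (its Brand Name concepts are indexed at
#'   construction)
#' @param min_token_chars minimum length of a one-token brand
#' @return `NULL` when nothing matches, else a list with
#'   `brand_concept_id` and `matched_tokens`
#' @export
match_brand <- function(drug_name, graph, min_token_chars = 3) {
  toks <- tokenize_name(drug_name)
  if (!length(toks)) return(NULL)
  cand <- graph$brand_by_first[[toks[1]]]
  if (is.null(cand)) return(NULL)
  best_id <- NA_integer_; best_len <- 0L
  for (i in cand) {
    bt <- graph$brand_tokens[[i]]
    n <- length(bt)
    if (n == 0 || n > length(toks)) next
    if (n == 1 && nchar(bt) < min_token_chars) next
    if (!identical(bt, toks[seq_len(n)])) next
    id <- graph$brand_ids[i]
    if (n > best_len || (n == best_len && id < best_id)) {
      best_len <- n; best_id <- id
    }
  }
  if (best_len == 0L) return(NULL)
  list(brand_concept_id = best_id, matched_tokens = best_len)
}

# decide forms for every source drug: registration-derived forms win where
# present; otherwise the voted decision for the drug's source form text.
decide_drug_doseforms <- function(drugs, links, tallies, alpha) {
  decided <- lapply(tallies, decide_doseforms, alpha = alpha)
  out <- list()
  for (drug in drugs) {
    reg_forms <- map_doseform_by_registration(drug, links)
    if (length(reg_forms)) {
      out[[drug$pzn]] <- reg_forms
    } else if (!is.null(drug$dose_form) && !is.na(drug$dose_form) &&
               nzchar(drug$dose_form)) {
      out[[drug$pzn]] <- decided[[norm_name(drug$dose_form)]] %||% integer()
    } else {
      out[[drug$pzn]] <- integer()
    }
  }
  out
}

#' Export vote tallies as a diagnostic table
#'
#' @param tallies list as produced by [collect_votes()]
#' @return data.frame with one row per (source form, dose form concept)
#' @export
tallies_as_table <- function(tallies) {
  rows <- lapply(tallies, function(t) {
    if (!length(t$votes)) return(NULL)
    data.frame(source_form = t$source_form,
               dose_form_concept_id = as.integer(names(t$votes)),
               weight = as.numeric(t$votes),
               contributing_drugs = t$contributing_drugs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(source_form = character(),
                                      dose_form_concept_id = integer(),
                                      weight = numeric(),
                                      contributing_drugs = integer())
  rownames(out) <- NULL
  out[order(out$source_form, out$dose_form_concept_id), , drop = FALSE]
}
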