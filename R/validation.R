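# Cross-validation of two independently produced mapping sets linked by EU
# drug registration numbers, using the finest-common-ancestor comparison,
# and the concept-class correspondence tally.

#' Link two mapping sets by EU drug registration number
#'
#' Each side is a data.frame with columns `source_code`, `eu_registration`
#' (raw, possibly a range -- normalized and expanded here) and
#' `target_concept_id`. One record is produced per (registration, left
#' source, right source) combination present on both sides; one-to-many
#' links therefore expand to all pairs. Registrations present on only one
#' side are logged and excluded.
#'
#' @param left_rows,right_rows data.frames as described
#' @return data.frame with one row per linked pair: `eu_registration`,
#'   `left_code`, `right_code`, plus list columns `left_targets`,
#'   `right_targets`
#' @export
link_by_registration <- function(left_rows, right_rows) {
  expand <- function(df, side) {
    recs <- lapply(seq_len(nrow(df)), function(i) {
      regs <- normalize_eu_registration(df$eu_registration[i])
      if (!length(regs)) return(NULL)
      data.frame(eu_registration = regs, source_code = df$source_code[i],
                 target_concept_id = as.integer(df$target_concept_id[i]),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    if (is.null(out)) out <- data.frame(eu_registration = character(),
                                        source_code = character(),
                                        target_concept_id = integer())
    out
  }
  l <- expand(left_rows, "left")
  r <- expand(right_rows, "right")
  shared <- intersect(unique(l$eu_registration), unique(r$eu_registration))
  dropped <- setdiff(union(unique(l$eu_registration),
                           unique(r$eu_registration)), shared)
  if (length(dropped)) {
    rx_log("warn", length(dropped), " registration(s) present on one side ",
           "only, excluded: ", paste(utils::head(dropped, 5), collapse = ", "))
  }
  out <- list()
  for (reg in c_sort(shared)) {
    lsub <- l[l$eu_registration == reg, , drop = FALSE]
    rsub <- r[r$eu_registration == reg, , drop = FALSE]
    for (lc in unique(lsub$source_code)) {
      for (rc in unique(rsub$source_code)) {
        out[[length(out) + 1]] <- data.frame(
          eu_registration = reg, left_code = lc, right_code = rc,
          left_targets = I(list(sort(unique(
            lsub$target_concept_id[lsub$source_code == lc])))),
          right_targets = I(list(sort(unique(
            rsub$target_concept_id[rsub$source_code == rc])))),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(eu_registration = character(), left_code = character(),
                      right_code = character(),
                      left_targets = I(list()), right_targets = I(list()))
  }
  rownames(res) <- NULL
  res
}

#' Compare one linked record by common concept ancestry
#'
#' Runs [finest_common_ancestors()] over the cross product of the record's
#' left and right target concepts, keeps the ancestors of maximal
#' granularity rank across all pairs, and records their concept class.
#' Disjoint ancestries (for instance a prodrug mapped against its active
#' moiety, two distinct ingredient concepts) yield class `"NONE"`.
#'
#' @param record one row of the output of [link_by_registration()]
#' @param graph a `concept_graph`
#' @return list with `eu_registration`, `left_targets`, `right_targets`,
#'   `left_class`, `right_class`, `common_ancestor_ids`,
#'   `common_ancestor_class`
#' @export
compare_record <- function(record, graph) {
  lt <- record$left_targets[[1]]
  rt <- record$right_targets[[1]]
  anc <- integer()
  for (a in lt) {
    for (b in rt) {
      if (!has_concept(graph, a) || !has_concept(graph, b)) next
      anc <- c(anc, finest_common_ancestors(graph, a, b)$concept_id)
    }
  }
  anc <- sort(unique(anc))
  side_class <- function(ids) {
    ids <- ids[ids %in% graph$ids]
    if (!length(ids)) return("NONE")
    cls <- concept_class_of(graph, ids)
    rk <- granularity_rank(cls)
    if (all(is.na(rk))) return("NONE")
    cls[which.max(rk)]
  }
  if (!length(anc)) {
    cls <- "NONE"
  } else {
    ranks <- granularity_rank(concept_class_of(graph, anc))
    if (all(is.na(ranks))) {
      cls <- "NONE"; anc <- integer()
    } else {
      anc <- anc[!is.na(ranks) & ranks == max(ranks, na.rm = TRUE)]
      cls <- concept_class_of(graph, anc[1])
    }
  }
  list(eu_registration = record$eu_registration,
       left_targets = lt, right_targets = rt,
       left_class = side_class(lt), right_class = side_class(rt),
       common_ancestor_ids = anc, common_ancestor_class = cls)
}

#' Validate two mapping sets against each other
#'
#' @param left_rows,right_rows see [link_by_registration()]
#' @param graph a `concept_graph`
#' @return list of validation records (see [compare_record()])
#' @export
validate_mappings <- function(left_rows, right_rows, graph) {
  records <- link_by_registration(left_rows, right_rows)
  lapply(seq_len(nrow(records)), function(i)
    compare_record(records[i, , drop = FALSE], graph))
}

#' Tally concept-class correspondences of validation records
#'
#' @param records list of validation records
#' @return data.frame with columns `left_class`, `ancestor_class`,
#'   `right_class`, `count`; counts partition the records
#' @export
tally_classes <- function(records) {
  if (!length(records)) {
    return(data.frame(left_class = character(), ancestor_class = character(),
                      right_class = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    left_class = vapply(records, `[[`, "", "left_class"),
    ancestor_class = vapply(records, `[[`, "", "common_ancestor_class"),
    right_class = vapply(records, `[[`, "", "right_class"),
    stringsAsFactors = FALSE)
  out <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          by = df, FUN = length)
  out <- out[order(out$ancestor_class, out$left_class, out$right_class,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract validation input from mapping rows and source drugs
#'
#' Convenience bridge: joins finalized mapping rows with the source drugs'
#' EU registration numbers to build one side of a validation comparison.
#'
#' @param rows mapping-row data.frame
#' @param drugs list of [source_drug()]s
#' @return data.frame with `source_code`, `eu_registration`,
#'   `target_concept_id`
#' @export
validation_side <- function(rows, drugs) {
  regs <- lapply(drugs, function(d) {
    if (is.null(d$eu_registration) || is.na(d$eu_registration)) return(NULL)
    data.frame(source_code = d$pzn, eu_registration = d$eu_registration,
               stringsAsFactors = FALSE)
  })
  regs <- do.call(rbind, regs)
  if (is.null(regs)) {
    return(data.frame(source_code = character(), eu_registration = character(),
                      target_concept_id = integer()))
  }
  mapped <- rows[rows$target_concept_id > 0,
                 c("source_code", "target_concept_id"), drop = FALSE]
  out <- merge(regs, mapped, by = "source_code")
  out[order(out$source_code, out$target_concept_id), , drop = FALSE]
}
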