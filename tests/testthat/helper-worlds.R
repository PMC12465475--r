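# Shared helpers: tiny graphs built in code and independent brute-force
# oracles the implementation is checked against.

concept_df <- function(ids, names = paste0("concept ", ids),
                       classes = "Ingredient", vocab = "RxNorm Extension",
                       standard = TRUE, codes = paste0("C", ids)) {
  data.frame(concept_id = ids, concept_name = names, vocabulary_id = vocab,
             concept_class_id = classes, standard_concept = standard,
             concept_code = codes, stringsAsFactors = FALSE)
}

rel_df <- function(from = integer(), to = integer(), rel = character()) {
  data.frame(concept_id_1 = from, concept_id_2 = to, relationship_id = rel,
             stringsAsFactors = FALSE)
}

# a 4-level is-a chain: 1 -> 2 -> 3 -> 4
chain_graph <- function() {
  concept_graph(
    concept_df(1:4, classes = c("Clinical Drug Box", "Clinical Drug",
                                "Clinical Drug Form", "Ingredient")),
    rel_df(1:3, 2:4, "RxNorm is a"))
}

# independent reachability oracle: boolean adjacency matrix closed by
# repeated multiplication (no traversal code shared with the package)
oracle_ancestors <- function(ids, edges, query) {
  n <- length(ids)
  A <- diag(n) > 0
  for (k in seq_len(nrow(edges))) {
    A[match(edges$concept_id_1[k], ids), match(edges$concept_id_2[k], ids)] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  sort(ids[A[match(query, ids), ]])
}

# random DAG over n nodes: edges only from lower to higher id, so acyclic
random_dag <- function(n, p = 0.03) {
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  take <- stats::runif(nrow(pairs)) < p
  rel_df(pairs[take, 1], pairs[take, 2], "RxNorm is a")
}

drug_classes_pool <- function() {
  c("Ingredient", "Clinical Drug Form", "Clinical Drug", "Branded Drug",
    "Clinical Drug Box", "Branded Drug Box", "Quantified Clinical Drug")
}

# exhaustive brand prefix scan, independent of the package's token index
oracle_brand <- function(name, brand_names, brand_ids, min_chars = 3) {
  nt <- tolower(strsplit(name, "[^[:alnum:]]+")[[1]])
  nt <- nt[nzchar(nt)]
  best <- NULL
  for (i in seq_along(brand_names)) {
    bt <- tolower(strsplit(brand_names[i], "[^[:alnum:]]+")[[1]])
    bt <- bt[nzchar(bt)]
    if (!length(bt) || length(bt) > length(nt)) next
    if (length(bt) == 1 && nchar(bt) < min_chars) next
    if (!identical(bt, nt[seq_along(bt)])) next
    cand <- list(id = brand_ids[i], len = length(bt))
    if (is.null(best) || cand$len > best$len ||
        (cand$len == best$len && cand$id < best$id)) best <- cand
  }
  best
}
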